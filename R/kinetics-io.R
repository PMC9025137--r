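#' Read and write redness-kinetics CSV files
#'
#' The on-disk format is a plain CSV with columns `time_h` and `a_ratio`,
#' preceded by `#`-prefixed metadata lines carrying the source label and the
#' storage condition (and any extra metadata such as the generator seed).
#' Files written by [write_kinetics()] round-trip exactly through
#' [read_kinetics()].
#'
#' @param x a [color_kinetics()].
#' @param path file path.
#' @return `write_kinetics()` returns `path` invisibly; `read_kinetics()`
#'   returns a [color_kinetics()].
#' @export
write_kinetics <- function(x, path) {
  stopifnot(inherits(x, "color_kinetics"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(source = x$source,
           T_C = x$conditions$T_C, pO2_pct = x$conditions$pO2_pct,
           aging_d = x$conditions$aging_d,
           angle_deg = x$conditions$angle_deg)
  meta <- x$meta[vapply(x$meta, is_number, logical(1))]
  hdr <- c(hdr, unlist(meta))
  writeLines(sprintf("# %s: %s", names(hdr), as.character(hdr)), con)
  writeLines("time_h,a_ratio", con)
  writeLines(sprintf("%s,%s",
                     format(x$times_h, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     format(x$values, digits = 15, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path))
    stop_parse("path", "kinetics file '%s' does not exist", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(text = lines[!is_meta])
  cond <- storage_conditions(
    T_C = as.numeric(meta$T_C %||% NA),
    pO2_pct = as.numeric(meta$pO2_pct %||% NA),
    aging_d = as.numeric(meta$aging_d %||% 14),
    angle_deg = as.numeric(meta$angle_deg %||% 0))
  extra <- meta[setdiff(names(meta),
                        c("source", "T_C", "pO2_pct", "aging_d", "angle_deg"))]
  color_kinetics(df$time_h, df$a_ratio, cond,
                 source = meta$source %||% "observed",
                 meta = lapply(extra, as.numeric))
}

#' Read and write a directory of kinetics runs
#'
#' A dataset directory holds one kinetics CSV per storage run plus a
#' `manifest.csv` listing the run conditions and file names, the layout the
#' calibration functions and the synthetic generator share.
#'
#' @param runs a named list of [color_kinetics()].
#' @param dir directory (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a named list of [color_kinetics()].
#' @export
write_dataset <- function(runs, dir) {
  stopifnot(is.list(runs), length(runs) > 0)
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    names(runs) <- sprintf("run_%02d", seq_along(runs))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    run = names(runs),
    T_C = vapply(runs, function(r) r$conditions$T_C, numeric(1)),
    pO2_pct = vapply(runs, function(r) r$conditions$pO2_pct, numeric(1)),
    aging_d = vapply(runs, function(r) r$conditions$aging_d, numeric(1)),
    angle_deg = vapply(runs, function(r) r$conditions$angle_deg, numeric(1)),
    source = vapply(runs, function(r) r$source, character(1)),
    file = paste0(names(runs), ".csv"))
  for (i in seq_along(runs))
    write_kinetics(runs[[i]], file.path(dir, manifest$file[i]))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop_parse("manifest", "no manifest.csv in '%s'", dir)
  manifest <- utils::read.csv(mf)
  runs <- lapply(manifest$file, function(f) read_kinetics(file.path(dir, f)))
  names(runs) <- manifest$run
  runs
}
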