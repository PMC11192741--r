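#' Write an incubation series to CSV
#'
#' Plain two-column CSV (`time_d`, `value`) preceded by `#key=value` header
#' lines carrying the series metadata, so a file round-trips through
#' [read_incubation_csv()] without loss.
#'
#' @param series An [incubation_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incubation_csv <- function(series, path) {
  meta <- c("observable", "dic_uM", "label_fraction", "headspace_ml",
            "water_ml", "subsample_ml", "poc_ug", "filter_vol_ml",
            "condition", "depth_m")
  hdr <- vapply(meta, function(k) {
    v <- attr(series, k)
    sprintf("#%s=%s", k, if (is.null(v)) "NA" else as.character(v))
  }, character(1))
  hdr <- c(hdr, sprintf("#subsample_times=%s",
                        paste(attr(series, "subsample_times"),
                              collapse = ";")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(series)[, c("time_d", "value")], con,
                   row.names = FALSE)
  invisible(path)
}

#' Read an incubation series from CSV
#'
#' @param path File written by [write_incubation_csv()] (or hand-built with
#'   the same layout).
#' @return An [incubation_series()].
#' @export
read_incubation_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else NA
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  num <- function(x) if (is.null(x) || x == "NA") NULL else as.numeric(x)
  st <- meta$subsample_times
  st <- if (is.null(st) || st == "") numeric(0)
    else as.numeric(strsplit(st, ";", fixed = TRUE)[[1]])
  incubation_series(
    df$time_d, df$value, observable = meta$observable,
    dic_uM = num(meta$dic_uM),
    label_fraction = as.numeric(meta$label_fraction),
    headspace_ml = as.numeric(meta$headspace_ml),
    water_ml = as.numeric(meta$water_ml),
    subsample_ml = as.numeric(meta$subsample_ml),
    subsample_times = st,
    poc_ug = num(meta$poc_ug), filter_vol_ml = num(meta$filter_vol_ml),
    condition = meta$condition,
    depth_m = suppressWarnings(as.numeric(meta$depth_m)))
}

#' Read a nanoSIMS ROI count table from CSV
#'
#' Expected columns: `roi_id`, `fov_id`, `morphotype`, `counts_12C`,
#' `counts_13C`, `counts_12C14N`, `counts_12C15N`, `is_background`.
#'
#' @param path CSV file path.
#' @return Data frame with the ROI schema.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("roi_id", "fov_id", "morphotype", "counts_12C", "counts_13C",
            "counts_12C14N", "counts_12C15N", "is_background")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("ROI table misses columns: ", paste(missing, collapse = ", "))
  df$is_background <- as.logical(df$is_background)
  df
}

#' Read a concentration-depth profile from CSV
#'
#' Expected columns: `depth_m`, `conc_uM`.
#'
#' @param path CSV file path.
#' @param species Species label for the profile.
#' @return A [depth_profile()].
#' @export
read_profile_csv <- function(path, species = "CH4") {
  df <- utils::read.csv(path)
  if (!all(c("depth_m", "conc_uM") %in% names(df)))
    stop("profile CSV needs columns depth_m, conc_uM")
  depth_profile(df$depth_m, df$conc_uM, species = species)
}
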