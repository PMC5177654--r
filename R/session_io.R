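# Session bundle I/O. A session is stored as plain tab-separated tables plus
# a JSON metadata file so every artifact stays inspectable with shell tools:
#   kinematics.tsv  t px py vx vy ax ay tx ty target_radius
#   spikes.tsv      unit_id channel b1 b2 ... (one row per unit)
#   trials.tsv      trial_kind onset_bin end_bin success target_x target_y
#                   hold_required acquire_bin
#   metadata.json   dt, task, seed, provenance, ...
# Files may be gzip-compressed (".gz" suffix); readers detect this.

fmt_num <- function(x) {
  # full-precision text so numeric round-trips are exact
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv <- function(df, path, gzip = FALSE) {
  if (gzip) path <- paste0(path, ".gz")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

find_table <- function(dir, stem) {
  for (p in file.path(dir, c(paste0(stem, ".tsv"), paste0(stem, ".tsv.gz")))) {
    if (file.exists(p)) return(p)
  }
  NULL
}

read_tsv_checked <- function(path, numeric_cols, required_cols) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (cn in intersect(numeric_cols, names(df))) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !(is.na(v) | v == "NA"))
      if (length(bad)) {
        stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                     path, cn, bad[1] + 1L))  # +1 for the header line
      }
      df[[cn]] <- num
    }
  }
  df
}

#' Write a session bundle to a directory
#'
#' @param session A `binned_session`.
#' @param dir Output directory (created if absent).
#' @param gzip Compress the tables with gzip.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(session$kinematics), file.path(dir, "kinematics.tsv"), gzip)
  spk <- session$spikes
  spk_df <- data.frame(unit_id = spk$unit_ids, channel = spk$channel_of_unit,
                       stringsAsFactors = FALSE)
  cnt <- as.data.frame(spk$counts)
  names(cnt) <- paste0("b", seq_len(ncol(spk$counts)))
  write_tsv(cbind(spk_df, cnt), file.path(dir, "spikes.tsv"), gzip)
  if (!is.null(session$trials)) {
    write_tsv(as.data.frame(session$trials), file.path(dir, "trials.tsv"), gzip)
  }
  meta <- session$metadata
  meta$dt <- session_dt(session)
  meta$n_bins <- n_bins(session)
  meta$n_units <- n_units(session)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' @param dir Directory written by [write_session()].
#' @return A `binned_session`.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop(sprintf("%s: no metadata.json", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dt <- meta$dt %||% .BIN_WIDTH_DEFAULT

  kin_path <- find_table(dir, "kinematics")
  if (is.null(kin_path)) stop(sprintf("%s: no kinematics table", dir))
  kin_cols <- c("t", "px", "py", "vx", "vy", "ax", "ay", "tx", "ty", "target_radius")
  kin <- read_tsv_checked(kin_path, kin_cols, c("px", "py"))
  kf <- kinematics_frame(kin$px, kin$py, kin$vx, kin$vy, kin$ax, kin$ay,
                         tx = kin$tx %||% NA_real_, ty = kin$ty %||% NA_real_,
                         target_radius = kin$target_radius %||% NA_real_,
                         dt = dt, t0 = if (is.null(kin$t)) 0 else kin$t[1])

  spk_path <- find_table(dir, "spikes")
  if (is.null(spk_path)) stop(sprintf("%s: no spikes table", dir))
  spk <- read_tsv_checked(spk_path, character(0), c("unit_id", "channel"))
  bin_cols <- grep("^b[0-9]+$", names(spk), value = TRUE)
  counts <- as.matrix(spk[, bin_cols, drop = FALSE])
  if (anyNA(counts)) {
    bad <- which(apply(counts, 1, anyNA))[1]
    stop(sprintf("%s: missing spike count at line %d", spk_path, bad + 1L))
  }
  block <- spike_count_block(counts, unit_ids = spk$unit_id,
                             channel_of_unit = spk$channel, bin_width = dt)

  trials <- NULL
  tr_path <- find_table(dir, "trials")
  if (!is.null(tr_path)) {
    tr <- read_tsv_checked(tr_path,
                           c("onset_bin", "end_bin", "target_x", "target_y",
                             "hold_required", "acquire_bin"),
                           c("trial_kind", "onset_bin", "end_bin", "success"))
    trials <- trial_table(tr$trial_kind, tr$onset_bin, tr$end_bin,
                          as.logical(tr$success), tr$target_x, tr$target_y,
                          tr$hold_required %||% 0.5,
                          tr$acquire_bin %||% NA_integer_)
  }
  meta$dt <- NULL; meta$n_bins <- NULL; meta$n_units <- NULL
  binned_session(kf, block, trials, metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
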