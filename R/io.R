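# Record I/O: wide CSV (time + 12 lead columns) and minimal WFDB
# (MIT format 16: text .hea header + interleaved int16 .dat, gain in
# adu/mV).  A metadata sidecar CSV carries the raw metadata and split.

.WFDB_GAIN <- 200          # adu per mV
.WFDB_FMT <- 16L

#' Write a 12-lead record to CSV or WFDB
#'
#' CSV layout: one row per sample with a leading `time` column (seconds)
#' and one column per lead.  WFDB layout: `<path>.hea` text header plus
#' `<path>.dat` with interleaved little-endian int16 samples at a gain of
#' 200 adu/mV.
#'
#' @param record an [ecg_record()].
#' @param path output file (CSV) or record base path without extension
#'   (WFDB).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  sig <- record$signal
  if (format == "csv") {
    df <- data.frame(time = (seq_len(ncol(sig)) - 1) / record$fs,
                     t(sig), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  adu <- round(sig * .WFDB_GAIN)
  adu[adu > 32767] <- 32767; adu[adu < -32768] <- -32768
  base <- basename(path)
  chks <- apply(adu, 1, function(v) {
    s <- sum(v) %% 65536
    if (s >= 32768) s - 65536 else s
  })
  hdr <- c(sprintf("%s 12 %g %d", base, record$fs, ncol(sig)),
           sprintf("%s.dat %d %d(0)/mV 16 0 %d %d 0 %s",
                   base, .WFDB_FMT, .WFDB_GAIN, adu[, 1], chks,
                   rownames(sig)))
  writeLines(hdr, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(adu)), con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 12-lead record from CSV or WFDB
#'
#' @param path CSV file or WFDB base path (with or without `.hea`).
#' @param format `"csv"` or `"wfdb"`; inferred from the extension when
#'   missing.
#' @param id record id; defaults to the file stem.
#' @return An [ecg_record()] (metadata empty; merge a sidecar separately).
#' @export
read_ecg <- function(path, format = NULL, id = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path)) "csv"
              else if (grepl("\\.hea$", path) ||
                       file.exists(paste0(path, ".hea"))) "wfdb"
              else stop("cannot infer format of ", path)
  if (is.null(id)) id <- sub("\\.(csv|hea)$", "", basename(path))
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    missing <- setdiff(LEAD_NAMES, names(df))
    if (length(missing))
      stop("CSV is missing lead(s): ", paste(missing, collapse = ", "))
    if (!"time" %in% names(df)) stop("CSV is missing the time column")
    dt <- diff(df$time[1:2])
    fs <- round(1 / dt)
    sig <- t(as.matrix(df[LEAD_NAMES]))
    return(ecg_record(sig, fs, id = id))
  }
  hea <- sub("\\.hea$", "", path)
  lines <- readLines(paste0(hea, ".hea"))
  top <- strsplit(lines[1], "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (nsig != 12) stop("expected 12 signals, header declares ", nsig)
  spec <- strsplit(lines[1 + seq_len(nsig)], "\\s+")
  gains <- vapply(spec, function(s) {
    g <- s[3]
    if (!grepl("/mV$", g)) stop("unknown units in WFDB header: ", g)
    as.numeric(sub("\\(.*", "", sub("/mV$", "", g)))
  }, numeric(1))
  leads <- vapply(spec, function(s) s[length(s)], character(1))
  con <- file(paste0(hea, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = nsig * nsamp, size = 2,
                 endian = "little", signed = TRUE)
  adu <- matrix(raw, nrow = nsig)
  sig <- adu / gains
  rownames(sig) <- leads
  missing <- setdiff(LEAD_NAMES, leads)
  if (length(missing))
    stop("WFDB record is missing lead(s): ", paste(missing, collapse = ", "))
  ecg_record(sig[LEAD_NAMES, , drop = FALSE], fs, id = id)
}

#' Write / read the metadata sidecar CSV
#'
#' Columns: `record_id, RAxis, TAxis, VentricularRate, QRSCount,
#' QRSDuration, split`.
#'
#' @param records list of [ecg_record()]s with metadata.
#' @param split factor aligned with `records` (optional).
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_metadata_sidecar <- function(records, path, split = NULL) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(record_id = r$id, RAxis = r$meta$RAxis, TAxis = r$meta$TAxis,
               VentricularRate = r$meta$VentricularRate,
               QRSCount = r$meta$QRSCount,
               QRSDuration = r$meta$QRSDuration)))
  df$split <- if (is.null(split)) NA else as.character(split)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_sidecar
#' @export
read_metadata_sidecar <- function(path) utils::read.csv(path)

#' Write / read a whole dataset directory
#'
#' One file (or WFDB pair) per record plus a `metadata.csv` sidecar.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"wfdb"`.
#' @return `dir` (write) or a list like [generate_dataset()]'s (read).
#' @export
write_dataset <- function(dataset, dir, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in dataset$records) {
    p <- file.path(dir, if (format == "csv") paste0(r$id, ".csv") else r$id)
    write_ecg(r, p, format)
  }
  write_metadata_sidecar(dataset$records, file.path(dir, "metadata.csv"),
                         dataset$split)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  md <- read_metadata_sidecar(file.path(dir, "metadata.csv"))
  records <- lapply(seq_len(nrow(md)), function(i) {
    id <- md$record_id[i]
    csv <- file.path(dir, paste0(id, ".csv"))
    r <- if (file.exists(csv)) read_ecg(csv, "csv", id = id)
         else read_ecg(file.path(dir, id), "wfdb", id = id)
    r$meta <- as.list(md[i, c("RAxis", "TAxis", "VentricularRate",
                              "QRSCount", "QRSDuration")])
    r
  })
  split <- if (all(is.na(md$split))) NULL
           else factor(md$split, levels = c("train", "val", "test"))
  list(records = records, split = split)
}
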