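# Reading spectra (mzXML via mzR, plus a TSV peak-list dialect for
# plain-text fixtures), sum spectra, and tabular output.

#' Construct a single MS scan
#'
#' @param rt retention time, seconds.
#' @param mz,intensity peak vectors (will be sorted by m/z).
#' @param ms_level MS level; only level-1 scans are consumed downstream.
#' @return a list with elements `rt`, `ms_level`, `peaks` (two-column
#'   matrix `mz`, `intensity`).
#' @export
scan <- function(rt, mz, intensity, ms_level = 1L) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  list(rt = as.numeric(rt), ms_level = as.integer(ms_level),
       peaks = cbind(mz = as.numeric(mz[o]),
                     intensity = as.numeric(intensity[o])))
}

#' Read centroided scans from an mzXML file
#'
#' Parsed with the proteowizard backend of \pkg{mzR}; supports the usual
#' base64-encoded peak arrays (32/64-bit, network byte order, uncompressed
#' or zlib). Scans are returned ordered by retention time.
#'
#' @param path mzXML file.
#' @return list of scans (see [scan()]).
#' @export
read_mzxml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  handle <- tryCatch(
    suppressWarnings(mzR::openMSfile(path, backend = "pwiz")),
    error = function(e) stop("failed to open '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  scans <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    pk <- tryCatch(mzR::peaks(handle, i), error = function(e)
      stop("corrupt peak data in '", path, "' at scan ", hdr$seqNum[i], ": ",
           conditionMessage(e), call. = FALSE))
    scans[[i]] <- scan(rt = hdr$retentionTime[i],
                       mz = pk[, 1], intensity = pk[, 2],
                       ms_level = hdr$msLevel[i])
  }
  scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
}

#' Read / write the TSV peak-list dialect
#'
#' A plain-text stand-in for mzXML used for small fixtures: tab-separated
#' columns `mz`, `intensity`, `rt`, `ms_level`, one row per centroid, rows
#' of one scan sharing `rt` and `ms_level`.
#'
#' @param path file path.
#' @return `read_peaklist_tsv` returns a list of scans.
#' @export
read_peaklist_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#")
  need <- c("mz", "intensity", "rt", "ms_level")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("peak-list TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(d$rt, d$ms_level)
  scans <- lapply(split(d, factor(key, levels = unique(key))), function(s) {
    scan(rt = s$rt[1], mz = s$mz, intensity = s$intensity,
         ms_level = s$ms_level[1])
  })
  names(scans) <- NULL
  scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
}

#' @rdname read_peaklist_tsv
#' @param scans list of scans.
#' @export
write_peaklist_tsv <- function(scans, path) {
  rows <- lapply(scans, function(s) {
    if (nrow(s$peaks) == 0L) return(NULL)
    data.frame(mz = s$peaks[, "mz"], intensity = s$peaks[, "intensity"],
               rt = s$rt, ms_level = s$ms_level)
  })
  write_result_table(do.call(rbind, rows), path, schema = "peak-list")
  invisible(path)
}

#' Read scans from any supported spectrum file
#'
#' Dispatches on file extension: `.mzXML` / `.mzxml` via [read_mzxml()],
#' `.tsv` via [read_peaklist_tsv()].
#'
#' @param path file path.
#' @return list of scans.
#' @export
read_scans <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mzxml = read_mzxml(path),
         tsv = read_peaklist_tsv(path),
         stop("unsupported spectrum file extension: '", ext, "'"))
}

#' Sum spectrum over a retention-time window
#'
#' Merges the centroids of all MS1 scans with `rt_window[1] <= rt <=
#' rt_window[2]` onto a fixed m/z grid: intensities are summed per grid
#' cell and the cell m/z is the intensity-weighted mean of its members.
#' The default 0.002 Th grid is an order of magnitude finer than the
#' narrowest integration window, so merging cannot move signal across
#' integration boundaries.
#'
#' @param scans list of scans.
#' @param rt_window numeric length 2, seconds.
#' @param grid_th merge grid width, Th.
#' @return a list of class `sum_spectrum` with elements `peaks` (data.frame
#'   `mz`, `intensity`, sorted by m/z), `rt_window`, `source_scan_count`.
#' @export
sum_spectra <- function(scans, rt_window, grid_th = 0.002) {
  stopifnot(length(rt_window) == 2L, rt_window[1] < rt_window[2])
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  lvl <- vapply(scans, `[[`, integer(1), "ms_level")
  sel <- lvl == 1L & rts >= rt_window[1] & rts <= rt_window[2]
  if (!any(sel)) {
    ms1 <- rts[lvl == 1L]
    stop(sprintf(
      "no MS1 scans in rt window [%g, %g]; available MS1 rt range: [%g, %g]",
      rt_window[1], rt_window[2],
      if (length(ms1)) min(ms1) else NA, if (length(ms1)) max(ms1) else NA))
  }
  mats <- lapply(scans[sel], `[[`, "peaks")
  mz <- unlist(lapply(mats, function(m) m[, "mz"]), use.names = FALSE)
  it <- unlist(lapply(mats, function(m) m[, "intensity"]), use.names = FALSE)
  keep <- it > 0
  mz <- mz[keep]; it <- it[keep]
  if (length(mz) == 0L) {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  } else {
    cell <- round(mz / grid_th)
    inten <- rowsum(it, cell, reorder = TRUE)
    wmz <- rowsum(it * mz, cell, reorder = TRUE) / inten
    peaks <- data.frame(mz = as.numeric(wmz), intensity = as.numeric(inten))
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(peaks = peaks, rt_window = as.numeric(rt_window),
                 source_scan_count = sum(sel)),
            class = "sum_spectrum")
}

#' @export
print.sum_spectrum <- function(x, ...) {
  cat(sprintf("<sum spectrum> rt [%g, %g] s, %d scans, %d peaks, TII %.4g\n",
              x$rt_window[1], x$rt_window[2], x$source_scan_count,
              nrow(x$peaks), sum(x$peaks$intensity)))
  invisible(x)
}

#' Write a result table as TSV with a schema comment line
#'
#' All tabular outputs share this writer: a `# silglyco <schema> v1` comment
#' line followed by a tab-separated table with header.
#'
#' @param df data.frame.
#' @param path output path.
#' @param schema short schema name recorded in the comment line.
#' @export
write_result_table <- function(df, path, schema = "table") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# silglyco ", schema, " v1"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
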