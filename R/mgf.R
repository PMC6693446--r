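# Minimal MGF (Mascot generic format) reader/writer for MS/MS peak lists.

#' Construct an MS/MS spectrum
#'
#' @param id Spectrum identifier.
#' @param precursor_mz Precursor m/z (may be `NA` for precursor-less
#'   entries; such spectra cannot be assigned).
#' @param precursor_charge Integer precursor charge (default 1).
#' @param peaks Data frame or two-column matrix of `mz`, `intensity`.
#' @return List of class `ms2_spectrum`; peaks are sorted by m/z and
#'   intensities must be non-negative.
#' @examples
#' ms2_spectrum("s1", 1043.55, 1, data.frame(mz = 278.11, intensity = 100))
#' @export
ms2_spectrum <- function(id, precursor_mz, precursor_charge = 1L, peaks) {
  peaks <- as.data.frame(peaks)
  if (ncol(peaks) >= 2L) names(peaks)[1:2] <- c("mz", "intensity")
  if (nrow(peaks) == 0L) {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  }
  if (any(peaks$intensity < 0)) stop("peak intensities must be non-negative")
  peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(
      id = as.character(id),
      precursor_mz = as.numeric(precursor_mz),
      precursor_charge = as.integer(precursor_charge),
      peaks = peaks
    ),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("MS2 spectrum '", x$id, "': precursor ",
    if (is.na(x$precursor_mz)) "absent" else sprintf("%.4f", x$precursor_mz),
    " (", x$precursor_charge, "+), ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Read / write MGF peak lists
#'
#' Supports the BEGIN IONS / END IONS block structure with TITLE, PEPMASS
#' (m/z, optional intensity) and CHARGE (e.g. `1+`) headers and
#' whitespace-separated peak lines. Unknown headers are ignored; a block
#' without PEPMASS yields a spectrum with `NA` precursor.
#'
#' @param path File path.
#' @param spectra List of `ms2_spectrum` objects (for the writer).
#' @return `read_mgf` returns a list of `ms2_spectrum`; `write_mgf` returns
#'   `path` invisibly.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in '", path, "'")
  }
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    get <- function(key) {
      v <- hdr[startsWith(hdr, paste0(key, "="))]
      if (length(v)) sub(paste0("^", key, "="), "", v[1]) else NA_character_
    }
    title <- get("TITLE")
    if (is.na(title)) title <- sprintf("spectrum_%d", i)
    pepmass <- get("PEPMASS")
    prec <- if (is.na(pepmass)) NA_real_ else
      as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1])
    charge_raw <- get("CHARGE")
    charge <- if (is.na(charge_raw)) 1L else
      as.integer(sub("\\+$", "", charge_raw))
    peak_lines <- block[!is_hdr]
    peaks <- if (length(peak_lines)) {
      vals <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"),
        function(x) as.numeric(x[1:2])))
      if (anyNA(vals)) stop("malformed MGF peak line in '", path, "'")
      data.frame(mz = vals[, 1], intensity = vals[, 2])
    } else {
      data.frame(mz = numeric(0), intensity = numeric(0))
    }
    ms2_spectrum(title, prec, charge, peaks)
  })
}

#' @rdname read_mgf
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "ms2_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id), con)
    if (!is.na(sp$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    }
    writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
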