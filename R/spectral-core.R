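#' Default wavelength grid
#'
#' The 176-band visible/near-infrared grid of the push-broom imaging
#' spectrometer the package targets: evenly spaced wavelengths from 393.7 nm
#' to 1001.4 nm (about 3.5 nm per band).
#'
#' @param n_bands Number of bands (default 176).
#' @param from,to Range endpoints in nm.
#' @return Numeric vector of strictly increasing wavelengths in nm.
#' @export
#' @examples
#' wl <- default_wavelength_grid()
#' length(wl)   # 176
#' range(wl)    # 393.7 1001.4
default_wavelength_grid <- function(n_bands = 176L, from = 393.7, to = 1001.4) {
  stopifnot(n_bands >= 2L, from < to)
  seq(from, to, length.out = n_bands)
}

#' Labelled spectra container
#'
#' Bundles a reflectance matrix with its wavelength grid, optional leaf
#' water potential labels (MPa, non-positive), sample identifiers and a
#' per-row provenance flag ("measured" or "cgan_generated").
#'
#' @param spectra Numeric matrix, one row per sample, one column per band.
#' @param grid Wavelength grid (nm), strictly increasing, length ncol(spectra).
#' @param psi Optional numeric vector of leaf water potentials in MPa
#'   (values must be <= 0), length nrow(spectra).
#' @param sample_ids Optional character vector of row identifiers.
#' @param provenance Character vector, one of "measured"/"cgan_generated"
#'   per row; a scalar is recycled.
#' @return An object of class \code{spectra_set}.
#' @export
spectra_set <- function(spectra, grid = default_wavelength_grid(ncol(spectra)),
                        psi = NULL, sample_ids = NULL,
                        provenance = "measured") {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  n <- nrow(spectra)
  if (length(grid) != ncol(spectra))
    stop("grid length (", length(grid), ") does not match band count (",
         ncol(spectra), ")")
  if (any(diff(grid) <= 0)) stop("wavelength grid must be strictly increasing")
  if (!all(is.finite(spectra))) stop("spectra contain non-finite values")
  if (!is.null(psi)) {
    psi <- as.numeric(psi)
    if (length(psi) != n) stop("psi length must equal the number of rows")
    if (any(!is.finite(psi))) stop("psi contains non-finite values")
    if (any(psi > 0)) stop("leaf water potential must be <= 0 MPa")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))
  if (length(sample_ids) != n) stop("sample_ids length must equal row count")
  provenance <- rep_len(as.character(provenance), n)
  bad <- setdiff(unique(provenance), c("measured", "cgan_generated"))
  if (length(bad)) stop("unknown provenance value: ", paste(bad, collapse = ", "))
  structure(list(spectra = spectra, grid = as.numeric(grid), psi = psi,
                 sample_ids = as.character(sample_ids),
                 provenance = provenance),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$spectra), " spectra x ", length(x$grid),
      " bands [", format(min(x$grid)), "-", format(max(x$grid)), " nm]\n",
      sep = "")
  if (is.null(x$psi)) {
    cat("  labels: none\n")
  } else {
    cat(sprintf("  psi: %.2f to %.2f MPa (mean %.2f)\n",
                min(x$psi), max(x$psi), mean(x$psi)))
  }
  tab <- table(x$provenance)
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$spectra)

#' Subset a spectra_set by row
#'
#' @param x A \code{spectra_set}.
#' @param i Row indices.
#' @return A \code{spectra_set} with the selected rows.
#' @export
subset_spectra <- function(x, i) {
  stopifnot(inherits(x, "spectra_set"))
  spectra_set(x$spectra[i, , drop = FALSE], grid = x$grid,
              psi = if (!is.null(x$psi)) x$psi[i],
              sample_ids = x$sample_ids[i], provenance = x$provenance[i])
}

#' Row-bind two spectra sets on a common grid
#'
#' @param a,b \code{spectra_set} objects on identical wavelength grids.
#' @return The concatenated \code{spectra_set}.
#' @export
bind_spectra <- function(a, b) {
  stopifnot(inherits(a, "spectra_set"), inherits(b, "spectra_set"))
  if (length(a$grid) != length(b$grid) ||
      max(abs(a$grid - b$grid)) > 1e-8)
    stop("wavelength grids differ; cannot bind")
  if (is.null(a$psi) != is.null(b$psi))
    stop("cannot bind a labelled set with an unlabelled set")
  spectra_set(rbind(a$spectra, b$spectra), grid = a$grid,
              psi = if (!is.null(a$psi)) c(a$psi, b$psi),
              sample_ids = make.unique(c(a$sample_ids, b$sample_ids)),
              provenance = c(a$provenance, b$provenance))
}

#' Reflectance calibration from white and dark reference frames
#'
#' Converts raw per-band sensor intensities to reflectance using a white
#' reference panel and a dark (lens-capped) frame:
#' \deqn{R_c = (I_o - I_d) / (I_w - I_d) \times R_w}
#' Negative calibrated values are clipped to 0 (reflectance below zero is
#' unphysical); values above 1 are retained, since the white panel is only
#' approximately 100 \% reflective and sensor noise can exceed it.
#'
#' @param original Raw intensity vector \eqn{I_o}.
#' @param white White-reference intensity vector \eqn{I_w}.
#' @param dark Dark-reference intensity vector \eqn{I_d}.
#' @param panel_reflectance Scalar reflectance of the white panel \eqn{R_w},
#'   about 1.0.
#' @return Numeric reflectance vector of the same length.
#' @export
#' @examples
#' calibrate_reflectance(c(0.5), c(0.9), c(0.1))  # 0.5
calibrate_reflectance <- function(original, white, dark,
                                  panel_reflectance = 1.0) {
  n <- length(original)
  if (length(white) != n || length(dark) != n)
    stop("original, white and dark frames must have equal length")
  stopifnot(is.numeric(panel_reflectance), length(panel_reflectance) == 1L,
            is.finite(panel_reflectance))
  denom <- white - dark
  zero <- which(denom == 0)
  if (length(zero))
    stop("white minus dark reference is zero at band index ", zero[1])
  r <- (original - dark) / denom * panel_reflectance
  pmax(r, 0)
}

#' Maximum-absolute-value normalization
#'
#' Divides each spectrum by its own maximum absolute value, so the largest
#' magnitude in the output is exactly 1. This is the per-spectrum reading of
#' max-abs normalization common in spectroscopy; \code{axis = "band"} instead
#' scales each wavelength column by its max-abs over the set.
#'
#' @param x Numeric vector (a single spectrum) or matrix (rows = spectra).
#' @param axis "spectrum" (default, row-wise) or "band" (column-wise;
#'   matrix input only).
#' @return Normalized vector or matrix of the same shape.
#' @export
#' @examples
#' max_abs_normalize(c(0, 0, 2))   # 0 0 1
#' max_abs_normalize(c(-4, 2))     # -1 0.5
max_abs_normalize <- function(x, axis = c("spectrum", "band")) {
  axis <- match.arg(axis)
  if (is.matrix(x)) {
    if (axis == "spectrum") {
      m <- apply(abs(x), 1L, max)
      if (any(m == 0)) stop("all-zero spectrum cannot be normalized (row ",
                            which(m == 0)[1], ")")
      x / m
    } else {
      m <- apply(abs(x), 2L, max)
      if (any(m == 0)) stop("all-zero band cannot be normalized (column ",
                            which(m == 0)[1], ")")
      sweep(x, 2L, m, "/")
    }
  } else {
    m <- max(abs(x))
    if (m == 0) stop("all-zero spectrum cannot be normalized")
    x / m
  }
}

#' Spectral angle between two spectra
#'
#' The Spectral Angle Mapper (SAM) similarity: the angle in radians between
#' two spectra viewed as vectors, \eqn{\arccos(\langle a,b\rangle /
#' (\|a\|\|b\|))}. Scale-invariant; 0 for identical shapes, \eqn{\pi/2} for
#' orthogonal ones.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return Angle in radians, in \eqn{[0, \pi]}.
#' @export
#' @examples
#' spectral_angle(c(1, 0), c(1, 1))  # pi/4
spectral_angle <- function(a, b) {
  if (length(a) != length(b)) stop("spectra must have equal length")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("spectral angle undefined for a zero spectrum")
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

band_col_names <- function(grid) sprintf("r%.1f", grid)

#' Read / write labelled spectra as CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' \code{sample_id, psi_mpa, r393.7, ..., r1001.4}: band columns are named by
#' wavelength so the grid is self-describing. A missing \code{psi_mpa}
#' column yields an unlabelled set. Labels may be stored in bar
#' (\code{unit = "bar"}); they are converted to MPa on load (1 MPa = 10 bar).
#'
#' @param path File path.
#' @param grid Expected wavelength grid; the file must carry exactly these
#'   bands (to 0.1 nm).
#' @param unit Unit of the psi column in the file: "MPa" (default) or "bar".
#' @return \code{read_spectra_csv}: a \code{spectra_set}.
#' @export
read_spectra_csv <- function(path, grid = default_wavelength_grid(),
                             unit = c("MPa", "bar")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  band_cols <- grep("^r[0-9]+(\\.[0-9]+)?$", names(df), value = TRUE)
  if (length(band_cols) != length(grid))
    stop("file has ", length(band_cols), " band columns; expected ",
         length(grid))
  file_wl <- as.numeric(sub("^r", "", band_cols))
  if (max(abs(file_wl - round(grid, 1))) > 0.05)
    stop("band wavelengths in file do not match the expected grid")
  mat <- as.matrix(df[band_cols])
  if (!is.numeric(mat) || anyNA(mat))
    stop("non-numeric reflectance cells in ", path)
  psi <- NULL
  if ("psi_mpa" %in% names(df)) {
    psi <- as.numeric(df$psi_mpa)
    if (anyNA(psi)) stop("non-numeric psi values in ", path)
    if (unit == "bar") psi <- psi / 10
  }
  prov <- if ("provenance" %in% names(df)) df$provenance else "measured"
  ids <- if ("sample_id" %in% names(df)) as.character(df$sample_id) else NULL
  spectra_set(mat, grid = grid, psi = psi, sample_ids = ids,
              provenance = prov)
}

#' @rdname read_spectra_csv
#' @param x A \code{spectra_set} to write.
#' @return \code{write_spectra_csv}: the path, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(x$psi)) df$psi_mpa <- x$psi
  mat <- x$spectra
  colnames(mat) <- band_col_names(x$grid)
  df <- cbind(df, as.data.frame(mat, optional = TRUE))
  df$provenance <- x$provenance
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
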