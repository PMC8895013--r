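#' Reflection data set
#'
#' @param hkl Integer matrix (n x 3) of Miller indices; no all-zero rows.
#' @param fo2 Observed intensities Fo^2 (arbitrary scale).
#' @param sigma Standard uncertainties sigma(Fo^2), all > 0.
#' @param wavelength Radiation wavelength in angstrom.
#' @return Object of class \code{reflection_set}.
#' @export
reflection_set <- function(hkl, fo2, sigma, wavelength = 0.71073) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  if (nrow(hkl) == 0) stop("reflection set must be non-empty")
  stopifnot(length(fo2) == nrow(hkl), length(sigma) == nrow(hkl))
  if (any(sigma <= 0)) stop("all sigma(Fo^2) must be positive")
  if (any(rowSums(abs(hkl)) == 0)) stop("(0,0,0) is not an observable reflection")
  structure(list(hkl = hkl, fo2 = as.numeric(fo2), sigma = as.numeric(sigma),
                 wavelength = wavelength),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections, wavelength %.5f A\n",
              nrow(x$hkl), x$wavelength))
  invisible(x)
}

#' Read a SHELX HKLF4 reflection file
#'
#' Fixed-format records (3I4, 2F8): h, k, l, Fo^2, sigma(Fo^2). Reading stops
#' at an all-zero terminator record or end of file. Records with negative
#' sigma are rejected with a warning naming the line.
#'
#' @param path File path.
#' @param wavelength Wavelength to attach (angstrom; HKLF4 files do not carry
#'   one).
#' @return A \code{\link{reflection_set}}.
#' @export
read_hkl <- function(path, wavelength = 0.71073) {
  lines <- readLines(path)
  h <- integer(0); k <- integer(0); l <- integer(0)
  fo2 <- numeric(0); sig <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (nchar(ln) < 28) ln <- formatC(ln, width = -28)
    hv <- suppressWarnings(as.integer(substr(ln, 1, 4)))
    kv <- suppressWarnings(as.integer(substr(ln, 5, 8)))
    lv <- suppressWarnings(as.integer(substr(ln, 9, 12)))
    fv <- suppressWarnings(as.numeric(substr(ln, 13, 20)))
    sv <- suppressWarnings(as.numeric(substr(ln, 21, 28)))
    if (any(is.na(c(hv, kv, lv, fv, sv))))
      stop(sprintf("malformed HKLF4 record at line %d: '%s'", i, lines[i]))
    if (hv == 0 && kv == 0 && lv == 0) break  # terminator
    if (sv <= 0) {
      warning(sprintf("line %d: non-positive sigma, record rejected", i))
      next
    }
    h <- c(h, hv); k <- c(k, kv); l <- c(l, lv)
    fo2 <- c(fo2, fv); sig <- c(sig, sv)
  }
  if (length(h) == 0) stop("no reflections read from ", path)
  message(sprintf("read %d reflections from %s", length(h), path))
  reflection_set(cbind(h, k, l), fo2, sig, wavelength)
}

#' Write a SHELX HKLF4 reflection file
#'
#' Bit-exact fixed-width output (3I4, 2F8.2) terminated by an all-zero
#' record.
#'
#' @param rs A \code{\link{reflection_set}}.
#' @param path Output file path.
#' @return \code{path} invisibly.
#' @export
write_hkl <- function(rs, path) {
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f",
                   rs$hkl[, 1], rs$hkl[, 2], rs$hkl[, 3], rs$fo2, rs$sigma)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0)), path)
  invisible(path)
}

#' Resolution of reflections
#'
#' sin(theta)/lambda = 0.5 * sqrt(h' G* h) in angstrom^-1.
#'
#' @param hkl Integer matrix (n x 3) or length-3 vector.
#' @param cell A \code{\link{unit_cell}}.
#' @return Numeric vector of sin(theta)/lambda values.
#' @export
resolution <- function(hkl, cell) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  Gs <- metric_tensors(cell)$Gstar
  0.5 * sqrt(rowSums((hkl %*% Gs) * hkl))
}

#' Significance filter on F/sigma(F)
#'
#' Retains reflections passing the significance rule; \code{t = 0} returns
#' the input unchanged (negative Fo^2 retained, handled by the weighted
#' least squares). For \code{t > 0} reflections with Fo^2 <= 0 are always
#' removed. Because the cutoff is stated on F while the data carry Fo^2,
#' the mapping is convention-dependent and configurable:
#' \describe{
#'   \item{\code{"fo2_over_sigma"}}{keep Fo^2 / sigma(Fo^2) >= t^2 (default).}
#'   \item{\code{"propagated"}}{keep 2 Fo^2 / sigma(Fo^2) >= t (first-order
#'     error propagation sigma(F) = sigma(Fo^2) / (2 F)).}
#' }
#'
#' @param rs A \code{\link{reflection_set}}.
#' @param t Threshold on F/sigma(F), >= 0.
#' @param rule Cutoff convention (see Details).
#' @return Filtered \code{\link{reflection_set}}.
#' @export
filter_significance <- function(rs, t, rule = c("fo2_over_sigma", "propagated")) {
  rule <- match.arg(rule)
  stopifnot(t >= 0)
  if (t == 0) return(rs)
  pos <- rs$fo2 > 0
  keep <- pos & switch(rule,
    fo2_over_sigma = rs$fo2 / rs$sigma >= t^2,
    propagated = 2 * rs$fo2 / rs$sigma >= t)
  if (!any(keep)) stop("significance filter removed every reflection")
  reflection_set(rs$hkl[keep, , drop = FALSE], rs$fo2[keep], rs$sigma[keep],
                 rs$wavelength)
}

#' Merge symmetry-equivalent reflections
#'
#' Optional utility (refinement uses the data as given): averages equivalent
#' observations, including Friedel mates, with inverse-variance weights.
#'
#' @param rs A \code{\link{reflection_set}}.
#' @param symmetry List of \code{\link{symop}} objects.
#' @return A merged \code{\link{reflection_set}}.
#' @export
merge_equivalents <- function(rs, symmetry) {
  n <- nrow(rs$hkl)
  canon <- character(n)
  for (i in seq_len(n)) {
    h <- rs$hkl[i, ]
    eqs <- unique(do.call(rbind, lapply(symmetry, function(op) {
      hp <- as.integer(round(h %*% op$R))
      rbind(hp, -hp)
    })))
    ord <- order(eqs[, 1], eqs[, 2], eqs[, 3])
    canon[i] <- paste(eqs[ord[1], ], collapse = " ")
  }
  groups <- split(seq_len(n), canon)
  out <- t(vapply(groups, function(ix) {
    w <- 1 / rs$sigma[ix]^2
    c(rs$hkl[ix[1], ], sum(w * rs$fo2[ix]) / sum(w), 1 / sqrt(sum(w)))
  }, numeric(5)))
  reflection_set(out[, 1:3, drop = FALSE], out[, 4], out[, 5], rs$wavelength)
}

#' Write a CIF-style fcf reflection file
#'
#' Reflection loop with h, k, l, Fo^2, sigma(Fo^2), k * Fc^2 and the
#' calculated phase in degrees.
#'
#' @param structure The refined \code{\link{crystal_structure}} (cell and
#'   wavelength are recorded in the header).
#' @param rs A \code{\link{reflection_set}}.
#' @param fc Complex calculated structure factors, one per reflection.
#' @param scale Scale factor k applied to Fc^2.
#' @param path Output file path.
#' @return \code{path} invisibly.
#' @export
write_fcf <- function(structure, rs, fc, scale, path) {
  stopifnot(length(fc) == nrow(rs$hkl))
  cl <- structure$cell
  phase <- (Arg(fc) * 180 / pi) %% 360
  hdr <- c("data_refinement",
           sprintf("_cell_length_a %.6f", cl$a),
           sprintf("_cell_length_b %.6f", cl$b),
           sprintf("_cell_length_c %.6f", cl$c),
           sprintf("_cell_angle_alpha %.5f", cl$alpha),
           sprintf("_cell_angle_beta %.5f", cl$beta),
           sprintf("_cell_angle_gamma %.5f", cl$gamma),
           sprintf("_diffrn_radiation_wavelength %.5f", structure$wavelength),
           "loop_",
           " _refln_index_h", " _refln_index_k", " _refln_index_l",
           " _refln_F_squared_meas", " _refln_F_squared_sigma",
           " _refln_F_squared_calc", " _refln_phase_calc")
  rows <- sprintf("%4d %4d %4d %12.4f %10.4f %12.4f %8.2f",
                  rs$hkl[, 1], rs$hkl[, 2], rs$hkl[, 3],
                  rs$fo2, rs$sigma, scale * Mod(fc)^2, phase)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read back an fcf reflection file
#'
#' Parses files written by \code{\link{write_fcf}}.
#'
#' @param path File path.
#' @return List with \code{hkl}, \code{fo2}, \code{sigma}, \code{fc2_scaled},
#'   \code{phase} (degrees).
#' @export
read_fcf <- function(path) {
  lines <- readLines(path)
  first <- grep("^\\s*-?[0-9]+\\s+-?[0-9]+\\s+-?[0-9]+\\s", lines)[1]
  if (is.na(first)) stop("no reflection rows found in ", path)
  m <- do.call(rbind, lapply(lines[first:length(lines)], function(ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
  list(hkl = m[, 1:3, drop = FALSE], fo2 = m[, 4], sigma = m[, 5],
       fc2_scaled = m[, 6], phase = m[, 7])
}
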