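#' Arithmetic wavenumber axis
#'
#' Builds the spectral coordinate grid `start, start + step, ...,
#' start + (count - 1) * step` (cm^-1) shared by endmembers and cubes.
#'
#' @param start first wavenumber (cm^-1).
#' @param step grid spacing (cm^-1), must be positive.
#' @param count number of points, at least 2.
#' @return an object of class `wn_axis` with fields `values`, `start`,
#'   `step`, `count`.
#' @export
#' @examples
#' ax <- make_wavenumber_axis(444.2, 1.98, 800)
#' range(ax$values)
make_wavenumber_axis <- function(start, step, count) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a single positive number", call. = FALSE)
  if (!is.numeric(count) || length(count) != 1L || count < 2 ||
      count != round(count))
    stop("`count` must be an integer >= 2", call. = FALSE)
  count <- as.integer(count)
  structure(
    list(values = start + step * (seq_len(count) - 1),
         start = start, step = step, count = count),
    class = "wn_axis")
}

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wn_axis> %d points, %.4g to %.4g cm^-1 (step %.4g)\n",
              x$count, x$values[1L], x$values[x$count], x$step))
  invisible(x)
}

#' Synthesise an endmember spectrum from Lorentzian peaks
#'
#' An endmember is a pure-component reference spectrum (e.g. fat or muscle)
#' from which phantom pixels are composed.  The intensity is a sum of
#' Lorentzian lines `A * g^2 / ((v - c)^2 + g^2)` (centre `c`, half-width
#' `g`, amplitude `A`) plus a linear baseline, clipped at zero.
#'
#' @param peaks list of numeric triples `c(center, width, amplitude)`
#'   (cm^-1, cm^-1, arbitrary units), or a 3-column matrix; may be empty.
#' @param baseline numeric pair `c(offset, slope)`; the slope is per cm^-1
#'   relative to the first axis point.
#' @param axis a [make_wavenumber_axis()] grid.
#' @param name label for the endmember (e.g. `"fat"`).
#' @return an object of class `endmember` with fields `axis`, `intensity`,
#'   `name`.
#' @export
#' @examples
#' ax <- make_wavenumber_axis(1000, 2, 401)
#' em <- synth_endmember(list(c(1440, 12, 1)), c(0.05, 0), ax, "lipid CH2")
synth_endmember <- function(peaks = list(), baseline = c(0, 0), axis,
                            name = "endmember") {
  stopifnot(inherits(axis, "wn_axis"))
  if (is.matrix(peaks)) peaks <- asplit(peaks, 1L)
  v <- axis$values
  y <- baseline[1L] + baseline[2L] * (v - v[1L])
  rng <- range(v)
  for (pk in peaks) {
    pk <- as.numeric(pk)
    if (length(pk) != 3L) stop("each peak must be c(center, width, amplitude)",
                               call. = FALSE)
    if (pk[2L] <= 0) stop("peak widths must be positive", call. = FALSE)
    if (pk[1L] < rng[1L] - 10 * pk[2L] || pk[1L] > rng[2L] + 10 * pk[2L])
      warning(sprintf("peak center %.1f cm^-1 lies far outside the axis range",
                      pk[1L]))
    y <- y + pk[3L] * pk[2L]^2 / ((v - pk[1L])^2 + pk[2L]^2)
  }
  y <- pmax(y, 0)
  structure(list(axis = axis, intensity = y, name = name), class = "endmember")
}

#' @export
print.endmember <- function(x, ...) {
  cat(sprintf("<endmember> '%s', %d points, max intensity %.3g\n",
              x$name, x$axis$count, max(x$intensity)))
  invisible(x)
}

#' @export
plot.endmember <- function(x, ...) {
  graphics::plot(x$axis$values, x$intensity, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "intensity (a.u.)", main = x$name, ...)
  invisible(x)
}

#' Built-in fat- and muscle-like endmember presets
#'
#' Synthetic stand-ins for measured porcine fat and muscle Raman spectra,
#' built from the canonical band assignments of lipids (1078, 1267, 1301,
#' 1440, 1655, 1747 cm^-1) and of proteins in muscle (855, 940, 1003
#' phenylalanine, 1250 amide III, 1450 CH2, 1660 amide I cm^-1).  The two
#' presets are strongly distinct (correlation well below 0.95), which is
#' all the phantom experiments require: spectral separation of fat from
#' muscle is trivial by construction.
#'
#' @param name `"fat"` or `"muscle"`.
#' @param axis a [make_wavenumber_axis()] grid.
#' @return an [synth_endmember()] object.
#' @export
#' @examples
#' ax <- make_wavenumber_axis(444.2, 15.98, 100)
#' fat <- endmember_preset("fat", ax)
#' muscle <- endmember_preset("muscle", ax)
#' cor(fat$intensity, muscle$intensity)
endmember_preset <- function(name = c("fat", "muscle"), axis) {
  name <- match.arg(name)
  peaks <- switch(name,
    fat = list(c(1078, 14, 0.50), c(1267, 12, 0.45), c(1301, 12, 0.80),
               c(1440, 16, 1.00), c(1655, 14, 0.55), c(1747, 12, 0.45)),
    muscle = list(c(855, 14, 0.35), c(940, 14, 0.30), c(1003, 10, 0.60),
                  c(1250, 20, 0.50), c(1340, 16, 0.35), c(1450, 16, 0.70),
                  c(1660, 18, 1.00)))
  synth_endmember(peaks, baseline = c(0.05, 0), axis = axis, name = name)
}
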