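#' Switching-function parameters
#'
#' Parameters of the rational switching function used to compute smooth
#' coordination numbers: \eqn{s(d) = (1 - (d/d_c)^6) / (1 - (d/d_c)^{12})},
#' which simplifies to \eqn{1 / (1 + (d/d_c)^6)}. The contribution of an atom
#' at distance \eqn{d} from the probe point decays from 1 (at the probe) to 0,
#' passing through 1/2 exactly at the cutoff \eqn{d_c}.
#'
#' Two cutoffs are used throughout the package: 1.4 Angstrom for K+ site
#' occupancy (about half the axial length of one binding site, so a centred
#' ion scores ~1 and an empty site ~0) and 3.2 Angstrom for oxygen
#' coordination and hydration (about the radius of the first hydration shell
#' of K+).
#'
#' @param d_c cutoff distance in Angstrom; must be positive.
#' @param numerator_exponent numerator exponent (default 6).
#' @param denominator_exponent denominator exponent; must be exactly twice
#'   the numerator exponent (default 12).
#' @return An object of class `switching_params`.
#' @examples
#' p <- switching_params(1.4)
#' switching_value(c(0, 1.4, 2.8), p)
#' @export
switching_params <- function(d_c, numerator_exponent = 6L,
                             denominator_exponent = 12L) {
  if (!is.numeric(d_c) || length(d_c) != 1L || !is.finite(d_c) || d_c <= 0)
    stop("`d_c` must be a single positive number (Angstrom)")
  n <- as.integer(numerator_exponent)
  m <- as.integer(denominator_exponent)
  if (m != 2L * n)
    stop("denominator_exponent must equal 2 * numerator_exponent")
  structure(list(d_c = as.numeric(d_c),
                 numerator_exponent = n,
                 denominator_exponent = m),
            class = "switching_params")
}

#' @export
print.switching_params <- function(x, ...) {
  cat(sprintf("switching function: (1 - (d/%.2f)^%d) / (1 - (d/%.2f)^%d)\n",
              x$d_c, x$numerator_exponent, x$d_c, x$denominator_exponent))
  invisible(x)
}

#' Evaluate the switching function
#'
#' Evaluates the rational 6/12 switching function in its singularity-free
#' form \eqn{1 / (1 + (d/d_c)^n)} with \eqn{n} the numerator exponent. The
#' naive form \eqn{(1 - x^6)/(1 - x^{12})} is 0/0 at \eqn{d = d_c}; the
#' reduced form is used so the function is continuous and strictly
#' decreasing everywhere.
#'
#' @param d distance(s) in Angstrom, each >= 0 (vectorised).
#' @param params a [switching_params()] object, or a single positive number
#'   taken as the cutoff `d_c` with default exponents.
#' @return numeric vector of values in (0, 1].
#' @examples
#' switching_value(0, 1.4)        # 1
#' switching_value(1.4, 1.4)      # 0.5 (limit of the 0/0 form)
#' switching_value(2.8, 1.4)      # 1/65
#' @export
switching_value <- function(d, params) {
  if (is.numeric(params)) params <- switching_params(params)
  if (!inherits(params, "switching_params"))
    stop("`params` must be a switching_params object or a cutoff distance")
  if (!is.numeric(d)) stop("`d` must be numeric")
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  1 / (1 + (d / params$d_c)^params$numerator_exponent)
}

# Bare hot-path version: no argument checks, d already a numeric vector.
.sw <- function(d, d_c, n = 6L) 1 / (1 + (d / d_c)^n)

#' Coordination number at a probe point
#'
#' Sums the switching function over a selection of atoms, giving a smooth
#' count of atoms within roughly `d_c` of the probe point. An empty
#' selection yields 0 by contract.
#'
#' @param probe numeric 3-vector, probe position in Angstrom.
#' @param coords an n x 3 matrix of atom positions (one row per atom of the
#'   selection), or a numeric 3-vector for a single atom.
#' @param params a [switching_params()] object or a cutoff distance.
#' @param contribution_threshold atoms contributing more than this are
#'   counted in `contributing_atoms` (default 0.01).
#' @return An object of class `coordination_result`: list with `value`
#'   (dimensionless, in `[0, n_atoms]`), `probe_point`, and
#'   `contributing_atoms`.
#' @examples
#' coordination_number(c(0, 0, 0), rbind(c(0, 0, 0), c(1.4, 0, 0)), 1.4)
#' @export
coordination_number <- function(probe, coords, params,
                                contribution_threshold = 0.01) {
  if (is.numeric(params)) params <- switching_params(params)
  probe <- as.numeric(probe)
  if (length(probe) != 3L || any(!is.finite(probe)))
    stop("`probe` must be a finite 3-vector")
  if (is.null(coords) || (is.matrix(coords) && nrow(coords) == 0L) ||
      length(coords) == 0L) {
    return(structure(list(value = 0, probe_point = probe,
                          contributing_atoms = 0L),
                     class = "coordination_result"))
  }
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3L, byrow = FALSE)
  if (ncol(coords) != 3L) stop("`coords` must be an n x 3 matrix")
  d <- sqrt((coords[, 1] - probe[1])^2 +
            (coords[, 2] - probe[2])^2 +
            (coords[, 3] - probe[3])^2)
  s <- .sw(d, params$d_c, params$numerator_exponent)
  structure(list(value = sum(s), probe_point = probe,
                 contributing_atoms = sum(s > contribution_threshold)),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("coordination number %.4f at (%.2f, %.2f, %.2f); %d contributing atoms\n",
              x$value, x$probe_point[1], x$probe_point[2], x$probe_point[3],
              x$contributing_atoms))
  invisible(x)
}
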