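#' Model parameters for the Barkai-Leibler receptor network
#'
#' Bundles the kinetic and concentration parameters of the stochastic
#' Barkai-Leibler (BL) model of chemotaxis receptor methylation. A receptor
#' carries \code{M} methylation sites; the methyltransferase CheR binds and
#' methylates inactive receptors, the methylesterase CheB binds and
#' demethylates active ones, and attractant (ligand) binding inactivates the
#' intermediate methylation levels.  Defaults are the E. coli parameter set
#' used throughout: \code{B0 = 0.28}, \code{Kr = 0.39}, \code{Kb = 0.54},
#' \code{KL = 0.1} (all uM), \code{nu_r = 0.75}, \code{nu_b = 0.6} (1/s),
#' cell volume 1e-15 L corresponding to 602.3 molecules per uM.
#'
#' @param M integer number of methylation sites (>= 1).
#' @param A0 total receptor concentration (uM).
#' @param R0 total CheR concentration (uM).
#' @param B0 total CheB concentration (uM).
#' @param Kr,Kb CheR/CheB dissociation constants (uM).
#' @param KL ligand dissociation constant of the intermediate levels (uM).
#' @param nu_r,nu_b methylation/demethylation catalytic rates (1/s).
#' @param L uniform ligand concentration (uM, >= 0).
#' @param V cell volume (L).
#' @param conversion molecules per uM at volume \code{V} (602.3 for 1e-15 L).
#' @return An object of class \code{bl_params}.
#' @examples
#' p <- bl_params()
#' receptor_count(p)   # N = round(A0 * conversion)
#' ell(p)              # dimensionless ligand level L/KL
#' @export
bl_params <- function(M = 2L, A0 = 13.6, R0 = 0.224, B0 = 0.28,
                      Kr = 0.39, Kb = 0.54, KL = 0.1,
                      nu_r = 0.75, nu_b = 0.6,
                      L = 2, V = 1e-15, conversion = 602.3) {
  M <- as.integer(M)
  stopifnot(length(M) == 1L, M >= 1L)
  num <- c(A0 = A0, R0 = R0, B0 = B0, Kr = Kr, Kb = Kb, KL = KL,
           nu_r = nu_r, nu_b = nu_b, L = L, V = V, conversion = conversion)
  if (any(!is.finite(num)))
    stop("all parameters must be finite numbers")
  pos <- num[setdiff(names(num), c("L", "R0"))]
  if (any(pos <= 0))
    stop("parameters must be strictly positive (except L, R0 which may be 0): ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  if (L < 0) stop("L must be >= 0")
  if (R0 < 0) stop("R0 must be >= 0")
  p <- c(list(M = M), as.list(num))
  if (round(p$A0 * p$conversion) < 1)
    stop("A0*conversion must give at least one receptor molecule")
  structure(p, class = "bl_params")
}

#' @export
print.bl_params <- function(x, ...) {
  cat("BL model parameters (M =", x$M, "methylation sites)\n")
  cat(sprintf("  A0 = %g uM (N = %d receptors), R0 = %g uM, B0 = %g uM\n",
              x$A0, receptor_count(x), x$R0, x$B0))
  cat(sprintf("  Kr = %g, Kb = %g, KL = %g uM; nu_r = %g, nu_b = %g 1/s\n",
              x$Kr, x$Kb, x$KL, x$nu_r, x$nu_b))
  cat(sprintf("  L = %g uM (ell = %g); alpha = %.4g\n",
              x$L, ell(x), zou_alpha(x)))
  invisible(x)
}

#' Number of receptor molecules in the cell
#'
#' @param params a \code{\link{bl_params}} object.
#' @return integer \code{round(A0 * conversion)}.
#' @export
receptor_count <- function(params) {
  as.integer(round(params$A0 * params$conversion))
}

#' Dimensionless ligand level
#'
#' @param params a \code{\link{bl_params}} object.
#' @return \code{L / KL}.
#' @export
ell <- function(params) params$L / params$KL

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named fields replaced and all
#' invariants re-checked.
#'
#' @param params a \code{\link{bl_params}} object.
#' @param ... named fields to replace (see \code{\link{bl_params}}).
#' @return a new \code{bl_params} object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(repl)] <- repl
  do.call(bl_params, p)
}

#' Elementary binding/unbinding rate constants
#'
#' The model is specified through dissociation constants; the stochastic
#' simulator additionally needs the individual on/off rates.  Off rates
#' default to values fast compared with the catalytic rates (time-scale
#' separation: every unbinding rate at least 10x max(nu_r, nu_b)), and the
#' on rates follow from the dissociation constants, e.g.
#' \code{k_plus = k_minus / Kr}.
#'
#' @param params a \code{\link{bl_params}} object.
#' @param k_minus CheR unbinding rate (1/s).
#' @param k_minus_p CheB unbinding rate (1/s).
#' @param k_d ligand unbinding rate (1/s).
#' @param check if TRUE, enforce the time-scale separation contract.
#' @return An object of class \code{bl_rates} with fields \code{k_plus},
#'   \code{k_minus}, \code{k_plus_p}, \code{k_minus_p}, \code{k_a},
#'   \code{k_d}.
#' @export
kinetic_rates <- function(params, k_minus = 10, k_minus_p = 10, k_d = 100,
                          check = TRUE) {
  stopifnot(k_minus > 0, k_minus_p > 0, k_d > 0)
  if (check) {
    floor_rate <- 10 * max(params$nu_r, params$nu_b)
    if (min(k_minus, k_minus_p, k_d) < floor_rate)
      warning("unbinding rates below 10*max(nu_r, nu_b); ",
              "time-scale separation assumption is weak")
  }
  structure(list(k_plus = k_minus / params$Kr, k_minus = k_minus,
                 k_plus_p = k_minus_p / params$Kb, k_minus_p = k_minus_p,
                 k_a = k_d / params$KL, k_d = k_d),
            class = "bl_rates")
}

#' Literature parameter sets for the downstream pathway
#'
#' Three published parameterisations of the receptor--CheY--motor pathway,
#' commonly labelled by first author: Morton-Firth, Rao and Kollmann.  Each
#' set carries the CheY phosphorylation rate \code{a_Y} (1/uM/s), CheY-P
#' dephosphorylation rate \code{lambda_Y} (1/s), total CheY \code{Y0} (uM),
#' receptor (CheA) concentration \code{A0} (uM), and the enzyme
#' concentrations and catalytic rates \code{R0}, \code{B0}, \code{nu_r},
#' \code{nu_b} that set the zero-order ultrasensitivity control parameter
#' \code{alpha = R0*nu_r/(B0*nu_b)}.
#'
#' @param set one of \code{"morton_firth"}, \code{"rao"}, \code{"kollmann"}.
#' @return a named list of parameter values.
#' @examples
#' zou_alpha(literature_params("morton_firth"))  # 0.547
#' @export
literature_params <- function(set = c("morton_firth", "rao", "kollmann")) {
  set <- match.arg(set)
  switch(set,
    morton_firth = list(a_Y = 3,   lambda_Y = 14.15, Y0 = 18,   A0 = 5,
                        R0 = 0.235, B0 = 2.27, nu_r = 0.819, nu_b = 0.155),
    rao          = list(a_Y = 100, lambda_Y = 30.1,  Y0 = 17.9, A0 = 5,
                        R0 = 0.3,   B0 = 2,    nu_r = 0.255, nu_b = 0.5),
    kollmann     = list(a_Y = 100, lambda_Y = 30.1,  Y0 = 9.7,  A0 = 5.3,
                        R0 = 0.16,  B0 = 0.28, nu_r = 0.39,  nu_b = 6.3))
}

#' Zero-order ultrasensitivity control parameter
#'
#' \code{alpha = R0*nu_r / (B0*nu_b)}, the ratio of maximal methylation to
#' maximal demethylation flux.  The ultrasensitive (Goldbeter-Koshland-like)
#' transition of the mean activity occurs at \code{alpha = 1} in the limit
#' of saturating receptor concentration.
#'
#' @param params a \code{\link{bl_params}} object or any list carrying
#'   \code{R0}, \code{nu_r}, \code{B0}, \code{nu_b}.
#' @return dimensionless \code{alpha}.
#' @export
zou_alpha <- function(params) {
  with(params, R0 * nu_r / (B0 * nu_b))
}

#' Critical CheR concentration
#'
#' The total CheR concentration at which the control parameter
#' \code{alpha = R0*nu_r/(B0*nu_b)} equals one, i.e. \code{B0*nu_b/nu_r}.
#' For the default E. coli parameter set this is 0.224 uM.
#'
#' @param params a \code{\link{bl_params}} object (R0 itself is ignored).
#' @return critical \code{R0} (uM).
#' @export
critical_R0 <- function(params) {
  with(params, B0 * nu_b / nu_r)
}

#' Activity probability of a methylation level
#'
#' Probability for a receptor at methylation level \code{m} to be in the
#' kinase-active conformation at ligand concentration \code{L}:
#' \code{a_m(L) = a_m(0) * K_m / (L + K_m)}, with the ideal conventions
#' \code{K_0 = 0} (the lowest level is always inactive) and
#' \code{K_M = Inf} (the highest level is always active).  Two conventions
#' are offered for the zero-ligand activity of the intermediate levels:
#' \describe{
#'   \item{\code{"ligation"}}{(default) an intermediate receptor is active
#'     exactly when unligated, so \code{a_m(0) = 1} and
#'     \code{a_m(L) = K_m/(L+K_m)}; this is the convention realised by the
#'     discrete reaction network, in which each intermediate level has one
#'     active (unligated) and one inactive (ligated) conformation.}
#'   \item{\code{"linear"}}{\code{a_m(0) = m/M}, a graded zero-ligand
#'     activity increasing with the methylation level.}
#' }
#'
#' @param m methylation level(s), integer in \code{0..M}.
#' @param params a \code{\link{bl_params}} object.
#' @param Km per-level ligand dissociation constant; defaults to
#'   \code{params$KL} for intermediate levels (ignored for m = 0 and m = M).
#' @param mode \code{"ligation"} or \code{"linear"} (see Details).
#' @return activity probabilities in [0, 1], vectorised over \code{m}.
#' @export
activity_probability <- function(m, params, Km = NULL,
                                 mode = c("ligation", "linear")) {
  mode <- match.arg(mode)
  M <- params$M
  if (any(m < 0 | m > M | m != round(m)))
    stop("m must be an integer in 0..M")
  if (is.null(Km)) Km <- params$KL
  a0 <- if (mode == "ligation") rep(1, length(m)) else m / M
  occ <- ifelse(is.finite(Km), Km / (params$L + Km), 1)
  out <- a0 * occ
  out[m == 0] <- 0   # K_0 = 0: always inactive
  out[m == M] <- 1   # K_M = Inf: always active (a_M(0) = 1 in both modes)
  out
}
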