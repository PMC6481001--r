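#' Dimensional model parameters
#'
#' Constructs the set of dimensional rate constants, receptor capacities and
#' diffusivities governing the MSC/chondrocyte/TGF-beta system. Defaults are
#' the representative literature estimates used throughout the package.
#'
#' @param Lambda1 MSC-to-chondrocyte differentiation rate (per minute).
#' @param fd Receptor-occupancy fraction above which an MSC commits to
#'   differentiation (dimensionless, in (0, 1)).
#' @param lambda3 Constitutive secretion rate of latent TGF-beta by
#'   chondrocytes (ng per minute per million cells).
#' @param lambda4 Binding rate of unbound latent TGF-beta to the
#'   hydrogel/ECM (per minute).
#' @param lambda5 Decay rate of unbound latent TGF-beta (per minute).
#' @param lambda6 Chemical activation rate of matrix-bound TGF-beta
#'   (per minute).
#' @param lambda7 Decay rate of matrix-bound latent TGF-beta (per minute).
#' @param lambda8 Decay rate of active TGF-beta (per minute).
#' @param lambda_m9,lambda_n9 Binding rates of active TGF-beta to MSC and
#'   chondrocyte receptors (per minute per (ng/mL)).
#' @param lambda_m10,lambda_n10 Internalisation rates of receptor-bound
#'   TGF-beta on MSCs and chondrocytes (per minute).
#' @param Ftot,Gtot Maximum receptor-bound TGF-beta mass per MSC and per
#'   chondrocyte (ng per million cells).
#' @param Dc,Da Diffusivities of unbound latent and active TGF-beta
#'   (m^2 per minute).
#'
#' @return An object of class `chondro_params`: a named list of the
#'   validated dimensional parameters.
#' @seealso [nondimensionalise()], [default_scales()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$lambda8                      # active TGF-beta decay, per minute
#' nondimensionalise(p)$lt8       # = 43 on the differentiation timescale
default_parameters <- function(Lambda1 = 6e-3,
                               fd = 0.01,
                               lambda3 = 1.094e-1,
                               lambda4 = 1e-1,
                               lambda5 = 6e-3,
                               lambda6 = 6e-2,
                               lambda7 = 6e-3,
                               lambda8 = 0.258,
                               lambda_m9 = 6e-2,
                               lambda_n9 = 6e-2,
                               lambda_m10 = 0.25,
                               lambda_n10 = 0.25,
                               Ftot = 6.23e-1,
                               Gtot = 6.23e-1,
                               Dc = 1.278e-9,
                               Da = 1.278e-9) {
  p <- list(Lambda1 = Lambda1, fd = fd, lambda3 = lambda3, lambda4 = lambda4,
            lambda5 = lambda5, lambda6 = lambda6, lambda7 = lambda7,
            lambda8 = lambda8, lambda_m9 = lambda_m9, lambda_n9 = lambda_n9,
            lambda_m10 = lambda_m10, lambda_n10 = lambda_n10,
            Ftot = Ftot, Gtot = Gtot, Dc = Dc, Da = Da)
  validate_params(p)
  structure(p, class = "chondro_params")
}

validate_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  if (p$fd >= 1)
    stop("parameter 'fd' must lie strictly between 0 and 1", call. = FALSE)
  invisible(p)
}

#' Characteristic scales for non-dimensionalisation
#'
#' Concentrations are scaled by `A0`, cell densities by `M0`, lengths by the
#' scaffold height `L` and time by the differentiation timescale `1/Lambda1`
#' carried in the dimensional parameter set.
#'
#' @param A0 Concentration scale (ng/mL).
#' @param M0 Cell-density scale (million cells/mL).
#' @param L Scaffold height (m); the full culture domain is `2 L`.
#'
#' @return An object of class `chondro_scales`.
#' @export
#' @examples
#' default_scales()
default_scales <- function(A0 = 1, M0 = 1, L = 2.4e-3) {
  s <- list(A0 = A0, M0 = M0, L = L)
  for (nm in names(s))
    if (!is.numeric(s[[nm]]) || length(s[[nm]]) != 1L ||
        !is.finite(s[[nm]]) || s[[nm]] <= 0)
      stop("scale '", nm, "' must be a single positive finite number",
           call. = FALSE)
  structure(s, class = "chondro_scales")
}

#' Map dimensional parameters to the dimensionless system
#'
#' Rescales every rate by the differentiation rate `Lambda1` (the unit of
#' dimensionless time), concentrations by `A0`, cell densities by `M0` and
#' diffusivities by `Lambda1 * L^2`. The solver operates exclusively on the
#' returned set. Two families of binding coefficients arise: `ltm9`/`ltn9`
#' weight the depletion of active TGF-beta (carrying the receptor capacity
#' `Ftot`/`Gtot` and cell-density scale), while `lhm9`/`lhn9` weight the
#' growth of the receptor-bound fractions; they satisfy
#' `ltm9 = lhm9 * Ftot * M0 / A0` (and likewise for the chondrocyte pair).
#'
#' @param dim A `chondro_params` object, see [default_parameters()].
#' @param scales A `chondro_scales` object, see [default_scales()].
#'
#' @return An object of class `chondro_dimless`: a named list with components
#'   `lt3`--`lt8` (production, matrix binding, decay and activation rates),
#'   `ltm9`, `ltn9`, `lhm9`, `lhn9` (receptor binding), `ltm10`, `ltn10`
#'   (internalisation), `Dtc`, `Dta` (diffusivities) and `fd` (threshold,
#'   carried through unchanged).
#' @export
#' @examples
#' dl <- nondimensionalise(default_parameters())
#' round(dl$lt3, 1)   # 18.2
#' dl$lt8             # 43
nondimensionalise <- function(dim = default_parameters(),
                              scales = default_scales()) {
  stopifnot(inherits(dim, "chondro_params"))
  if (!inherits(scales, "chondro_scales"))
    scales <- do.call(default_scales, as.list(scales))
  validate_params(unclass(dim))
  L1 <- dim$Lambda1
  dl <- list(
    lt3   = scales$M0 * dim$lambda3 / (scales$A0 * L1),
    lt4   = dim$lambda4 / L1,
    lt5   = dim$lambda5 / L1,
    lt6   = dim$lambda6 / L1,
    lt7   = dim$lambda7 / L1,
    lt8   = dim$lambda8 / L1,
    ltm9  = scales$M0 * dim$Ftot * dim$lambda_m9 / L1,
    ltn9  = scales$M0 * dim$Gtot * dim$lambda_n9 / L1,
    lhm9  = scales$A0 * dim$lambda_m9 / L1,
    lhn9  = scales$A0 * dim$lambda_n9 / L1,
    ltm10 = dim$lambda_m10 / L1,
    ltn10 = dim$lambda_n10 / L1,
    Dtc   = dim$Dc / (L1 * scales$L^2),
    Dta   = dim$Da / (L1 * scales$L^2),
    fd    = dim$fd
  )
  structure(dl, class = "chondro_dimless")
}

#' Convert dimensionless time to hours
#'
#' One unit of dimensionless time is the differentiation timescale
#' `1/Lambda1`; at the default rate this is about 2.78 hours.
#'
#' @param t_star Dimensionless time(s), non-negative.
#' @param dim A `chondro_params` object supplying `Lambda1` (per minute).
#'
#' @return Time(s) in hours.
#' @export
#' @examples
#' dimensional_time(10)    # ~27.8 h
dimensional_time <- function(t_star, dim = default_parameters()) {
  stopifnot(is.numeric(t_star), all(t_star >= 0 | is.na(t_star)))
  t_star / dim$Lambda1 / 60
}

#' @export
print.chondro_params <- function(x, ...) {
  cat("Dimensional parameters (rates per minute, masses ng, cells Mio):\n")
  print(format(unlist(unclass(x)), digits = 4), quote = FALSE)
  invisible(x)
}

#' @export
print.chondro_dimless <- function(x, ...) {
  cat("Dimensionless parameters (time unit = 1/Lambda1):\n")
  print(format(unlist(unclass(x)), digits = 4), quote = FALSE)
  invisible(x)
}
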