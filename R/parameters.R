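#' Model parameters for the ppGpp / growth / fatty-acid / biosensor model
#'
#' Constructs a validated parameter set for the nine-variable kinetic model of
#' the stringent response during batch growth of *E. coli*. The defaults are
#' the package's calibrated reference set (see
#' \code{\link{calibrate_reference_set}} and the methods vignette): rate and
#' Michaelis constants were anchored to a ~30 min doubling time, an
#' exponential-phase ppGpp level near 50 uM, a peak ppGpp inside the
#' observable 50--1000 uM window, and a 3-fold 24-h fatty-acid yield ratio
#' between the low-Tes and high-Tes producer lines.
#'
#' Units: time in minutes; intracellular concentrations (Acyl-ACP, ppGpp and
#' their Michaelis/inhibition constants) in uM; culture fatty acid in mg/l;
#' cell number in OD600 units; \code{V_tes} in mg/l/OD/min with \code{k_fa}
#' converting that culture-normalised rate into intracellular uM/min.
#'
#' @param Vm_FAS Maximal fatty-acid-synthesis (FAS) rate, uM/min.
#' @param Km_ACP Michaelis constant of FAS for free ACP, uM.
#' @param Km_AcCoA Michaelis constant of FAS for acetyl-CoA, uM.
#' @param Ki_AcylACP Feedback-inhibition constant of FAS by Acyl-ACP, uM.
#' @param ACP_const Effective free-ACP concentration, uM (held constant;
#'   default saturating, see Details).
#' @param AcCoA_const Effective acetyl-CoA concentration, uM (held constant).
#' @param ACP_conserved If \code{TRUE}, free ACP is coupled to Acyl-ACP by the
#'   conservation \code{ACP_free = ACP_const - AcylACP} (floored at 0) instead
#'   of being held constant. Default \code{FALSE}.
#' @param Vm_PLS Maximal phospholipid-synthesis (PLS, PlsB) rate, uM/min.
#' @param Km_AcylACP Michaelis constant of PlsB for Acyl-ACP, uM.
#' @param Ki_ppGpp Inhibition constant of PLS by ppGpp, uM.
#' @param n_hill Hill coefficient of PLS inhibition by ppGpp (>= 1).
#' @param V_tes Thioesterase (Tes) activity, mg/l/OD/min. 0.08 is the
#'   endogenous (control-line) level; see \code{\link{line_presets}}.
#' @param Km_tes Michaelis constant of Tes for Acyl-ACP, uM.
#' @param k_fa Volume coefficient converting the culture-normalised FA
#'   production rate (mg/l/OD/min) into an intracellular Acyl-ACP drain
#'   (uM/min).
#' @param K_gr Maximal specific growth-rate constant, 1/min.
#' @param V0 Minimal PLS rate required to sustain growth, uM/min.
#' @param k_nutr Depletion rate constant of the growth-supporting nutrient
#'   \code{nutr}, 1/(OD min).
#' @param k_lim Depletion rate constant of the exponential-phase-limiting
#'   nutrient \code{lim}, 1/(OD min).
#' @param kp_ppGpp ppGpp synthesis rate constant per unit ribosome activity,
#'   uM/min.
#' @param km_ppGpp lim-dependent ppGpp hydrolysis rate constant, 1/min.
#' @param k0m_ppGpp Background ppGpp hydrolysis rate constant, 1/min.
#' @param Km_Ac_pp Acyl-ACP half-saturation of ppGpp hydrolysis, uM. The
#'   calibrated value sets the 3-fold line1:line3 yield ratio.
#' @param kp_rib Ribosome-activity synthesis constant, 1/min.
#' @param km_rib Ribosome-activity decay constant, 1/min.
#' @param Ki_P1P2_ppGpp Inhibition constant of the tandem rRNA P1/P2 promoter
#'   by ppGpp, uM.
#' @param m_hill Hill coefficient of P1/P2 inhibition (tandem promoter), 2.
#' @param k_I Turnover rate constant of the repressor I, 1/min.
#' @param k_GFP Turnover rate constant of GFP, 1/min (0.1).
#' @param Ki_I Inhibition constant of GFP expression by I (relative units).
#' @param l_hill Hill coefficient of GFP repression by I (tetramer), 4.
#' @param depletion_floor Saturation floor in the nutrient-depletion terms
#'   (0.001), preventing negative nutrient levels.
#'
#' @details The FAS substrates ACP and acetyl-CoA are not dynamic variables of
#' the nine-ODE system; by default they enter as constant, saturating
#' concentrations so their Michaelis factors are close to 1. Setting
#' \code{ACP_conserved = TRUE} switches to the alternative reading in which
#' free ACP is depleted by Acyl-ACP through a conservation law.
#'
#' @return An object of class \code{ppgpp_parameters} (a named list).
#' @seealso \code{\link{load_parameters}}, \code{\link{line_presets}},
#'   \code{\link{sensor_preset}}
#' @examples
#' p <- model_parameters()
#' p_hiTes <- model_parameters(V_tes = 110)
#' @export
model_parameters <- function(Vm_FAS = 10,
                             Km_ACP = 1,
                             Km_AcCoA = 1,
                             Ki_AcylACP = 1,
                             ACP_const = 100,
                             AcCoA_const = 100,
                             ACP_conserved = FALSE,
                             Vm_PLS = 20,
                             Km_AcylACP = 1,
                             Ki_ppGpp = 200,
                             n_hill = 2,
                             V_tes = 0.08,
                             Km_tes = 1,
                             k_fa = 2,
                             K_gr = 0.03,
                             V0 = 0.05,
                             k_nutr = 0.0015,
                             k_lim = 0.023,
                             kp_ppGpp = 850,
                             km_ppGpp = 14,
                             k0m_ppGpp = 1,
                             Km_Ac_pp = 0.0092568463001869612,
                             kp_rib = 0.03,
                             km_rib = 0.02,
                             Ki_P1P2_ppGpp = 45,
                             m_hill = 2,
                             k_I = 0.1,
                             k_GFP = 0.1,
                             Ki_I = 0.3,
                             l_hill = 4,
                             depletion_floor = 0.001) {
  p <- list(
    Vm_FAS = Vm_FAS, Km_ACP = Km_ACP, Km_AcCoA = Km_AcCoA,
    Ki_AcylACP = Ki_AcylACP, ACP_const = ACP_const, AcCoA_const = AcCoA_const,
    ACP_conserved = isTRUE(ACP_conserved),
    Vm_PLS = Vm_PLS, Km_AcylACP = Km_AcylACP, Ki_ppGpp = Ki_ppGpp,
    n_hill = n_hill, V_tes = V_tes, Km_tes = Km_tes, k_fa = k_fa,
    K_gr = K_gr, V0 = V0, k_nutr = k_nutr, k_lim = k_lim,
    kp_ppGpp = kp_ppGpp, km_ppGpp = km_ppGpp, k0m_ppGpp = k0m_ppGpp,
    Km_Ac_pp = Km_Ac_pp, kp_rib = kp_rib, km_rib = km_rib,
    Ki_P1P2_ppGpp = Ki_P1P2_ppGpp, m_hill = m_hill,
    k_I = k_I, k_GFP = k_GFP, Ki_I = Ki_I, l_hill = l_hill,
    depletion_floor = depletion_floor
  )
  validate_parameters(p)
  structure(p, class = "ppgpp_parameters")
}

## Documented unit per parameter key; used by load_parameters() to check
## optional unit annotations and by print().
parameter_units <- function() {
  c(Vm_FAS = "uM/min", Km_ACP = "uM", Km_AcCoA = "uM", Ki_AcylACP = "uM",
    ACP_const = "uM", AcCoA_const = "uM", ACP_conserved = "logical",
    Vm_PLS = "uM/min", Km_AcylACP = "uM", Ki_ppGpp = "uM",
    n_hill = "dimensionless", V_tes = "mg/l/OD/min", Km_tes = "uM",
    k_fa = "uM/min per mg/l/OD/min", K_gr = "1/min", V0 = "uM/min",
    k_nutr = "1/(OD min)", k_lim = "1/(OD min)", kp_ppGpp = "uM/min",
    km_ppGpp = "1/min", k0m_ppGpp = "1/min", Km_Ac_pp = "uM",
    kp_rib = "1/min", km_rib = "1/min", Ki_P1P2_ppGpp = "uM",
    m_hill = "dimensionless", k_I = "1/min", k_GFP = "1/min",
    Ki_I = "dimensionless", l_hill = "dimensionless",
    depletion_floor = "dimensionless")
}

## Strictly positive rate/Michaelis constants. Hill coefficients >= 1.
validate_parameters <- function(p) {
  keys <- names(parameter_units())
  missing <- setdiff(keys, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(p), keys)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  num <- setdiff(keys, "ACP_conserved")
  for (k in num) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", k, "' must be a finite numeric scalar")
  }
  hill <- c("n_hill", "m_hill", "l_hill")
  for (k in hill)
    if (p[[k]] < 1) stop("parameter '", k, "' must be >= 1")
  nonneg <- c("V_tes", "depletion_floor", "k_nutr", "k_lim", "K_gr")
  pos <- setdiff(num, c(hill, nonneg))
  for (k in pos)
    if (p[[k]] <= 0) stop("parameter '", k, "' must be strictly positive")
  for (k in nonneg)
    if (p[[k]] < 0) stop("parameter '", k, "' must be non-negative")
  invisible(p)
}

#' @export
print.ppgpp_parameters <- function(x, ...) {
  cat("ppGpp batch-growth model parameters\n")
  units <- parameter_units()
  num <- setdiff(names(units), "ACP_conserved")
  df <- data.frame(value = vapply(num, function(k) x[[k]], numeric(1)),
                   unit = unname(units[num]))
  print(df, ...)
  cat("ACP coupling:",
      if (isTRUE(x$ACP_conserved)) "conserved (ACP_free = ACP_const - AcylACP)"
      else "constant (saturating)", "\n")
  invisible(x)
}

#' Read a model parameter file
#'
#' Reads a flat YAML key/value file whose keys are the field names of
#' \code{\link{model_parameters}}. Keys absent from the file are filled from
#' the shipped reference set (a notice is emitted naming them). Values may be
#' bare numbers or strings of the form \code{"<number> <unit>"}; an annotated
#' unit must match the documented unit for that key. Unknown keys and
#' non-numeric values are rejected with an error naming the offending key.
#'
#' @param path Path to a YAML parameter file. An empty file yields the full
#'   reference set.
#' @param quiet Suppress the notice listing defaulted keys.
#' @return A validated \code{ppgpp_parameters} object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("V_tes: 19", "Ki_I: 0.1"), f)
#' p <- load_parameters(f, quiet = TRUE)
#' @export
load_parameters <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("parameter file must be a flat key/value mapping")
  units <- parameter_units()
  unknown <- setdiff(names(raw), names(units))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  defaults <- model_parameters()
  p <- unclass(defaults)
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k == "ACP_conserved") {
      if (!is.logical(v) || length(v) != 1L)
        stop("parameter 'ACP_conserved' must be TRUE or FALSE")
      p[[k]] <- v
      next
    }
    if (is.character(v) && length(v) == 1L) {
      parts <- strsplit(trimws(v), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(num))
        stop("non-numeric value for parameter '", k, "': ", v)
      if (length(parts) > 1) {
        unit <- paste(parts[-1], collapse = " ")
        if (unit != units[[k]])
          stop("unit mismatch for parameter '", k, "': got '", unit,
               "', documented unit is '", units[[k]], "'")
      }
      v <- num
    }
    if (!is.numeric(v) || length(v) != 1L)
      stop("non-numeric value for parameter '", k, "'")
    p[[k]] <- as.numeric(v)
  }
  validate_parameters(p)
  filled <- setdiff(setdiff(names(units), names(raw)), "ACP_conserved")
  if (!quiet && length(filled))
    message("load_parameters: ", length(filled),
            " key(s) filled from the reference set: ",
            paste(filled, collapse = ", "))
  structure(p, class = "ppgpp_parameters")
}

#' Write a model parameter file
#'
#' Serialises a parameter set to the flat YAML dialect read by
#' \code{\link{load_parameters}} (numeric values, full precision).
#'
#' @param p A \code{ppgpp_parameters} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "ppgpp_parameters"))
  keys <- names(parameter_units())
  lines <- vapply(keys, function(k) {
    v <- p[[k]]
    val <- if (is.logical(v)) (if (v) "true" else "false")
           else format(v, digits = 17)
    paste0(k, ": ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
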