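## State vector layout is fixed; all integration and I/O code relies on it.
state_names <- function() {
  c("AcylACP", "FA", "N", "nutr", "lim", "ppGpp", "rib", "I", "GFP")
}

#' Construct a model state vector
#'
#' The nine dynamic variables of the model: intracellular Acyl-ACP (uM),
#' culture fatty acid FA (mg/l), cell number N (OD600 units), the two
#' relative nutrient pools \code{nutr} and \code{lim}, ppGpp (uM), relative
#' ribosome activity \code{rib}, and the relative repressor \code{I} and
#' reporter \code{GFP} amounts (both in [0, 1]).
#'
#' @param AcylACP,FA,N,nutr,lim,ppGpp,rib,I,GFP Non-negative scalars.
#' @return A named numeric vector of class \code{ppgpp_state}.
#' @seealso \code{\link{pre_equilibrate}} for initial conditions consistent
#'   with established exponential growth.
#' @export
model_state <- function(AcylACP = 0.5, FA = 0, N = 0.01, nutr = 1, lim = 1,
                        ppGpp = 50, rib = 0.9, I = 1, GFP = 0) {
  s <- c(AcylACP = AcylACP, FA = FA, N = N, nutr = nutr, lim = lim,
         ppGpp = ppGpp, rib = rib, I = I, GFP = GFP)
  validate_state(s)
  structure(s, class = "ppgpp_state")
}

validate_state <- function(s) {
  if (!all(state_names() %in% names(s)))
    stop("state must contain: ", paste(state_names(), collapse = ", "))
  s <- s[state_names()]
  if (any(!is.finite(s))) stop("non-finite state component")
  if (any(s < 0))
    stop("negative state component: ",
         paste(names(s)[s < 0], collapse = ", "))
  for (k in c("I", "GFP", "nutr", "lim"))
    if (s[[k]] > 1 + 1e-9) stop("state component '", k, "' exceeds 1")
  invisible(s)
}

## Effective free-ACP concentration under either coupling mode.
acp_free <- function(AcylACP, p) {
  if (isTRUE(p$ACP_conserved)) pmax(p$ACP_const - AcylACP, 0) else p$ACP_const
}

#' Fatty-acid synthesis rate
#'
#' Lumped FAS rate law: proportional to ribosome activity, Michaelis-Menten
#' in the substrates ACP and acetyl-CoA, with linear (non-cooperative)
#' product feedback inhibition by Acyl-ACP.
#'
#' @param state Named state vector (needs \code{AcylACP}, \code{rib}).
#' @param p A \code{ppgpp_parameters} object.
#' @return FAS flux in uM/min.
#' @export
v_fas <- function(state, p) {
  AcylACP <- state[["AcylACP"]]; rib <- state[["rib"]]
  if (AcylACP < 0 || rib < 0) stop("negative state component")
  ACP <- acp_free(AcylACP, p)
  p$Vm_FAS * rib *
    ACP / (ACP + p$Km_ACP) *
    p$AcCoA_const / (p$AcCoA_const + p$Km_AcCoA) /
    (1 + AcylACP / p$Ki_AcylACP)
}

#' Phospholipid synthesis rate
#'
#' PlsB-limited PLS rate: proportional to ribosome activity,
#' Michaelis-Menten in Acyl-ACP, and inhibited by ppGpp through a Hill
#' function (cooperative, reflecting regulation of PlsB at several levels).
#'
#' @inheritParams v_fas
#' @return PLS flux in uM/min.
#' @export
v_pls <- function(state, p) {
  AcylACP <- state[["AcylACP"]]; rib <- state[["rib"]]
  ppGpp <- state[["ppGpp"]]
  if (AcylACP < 0 || rib < 0 || ppGpp < 0) stop("negative state component")
  p$Vm_PLS * rib * AcylACP / (AcylACP + p$Km_AcylACP) /
    (1 + (ppGpp / p$Ki_ppGpp)^p$n_hill)
}

#' Free fatty-acid release rate (thioesterase)
#'
#' Michaelis-Menten rate of Acyl-ACP thioester hydrolysis by Tes, in
#' culture-normalised units (mg/l/OD/min). Vectorised over \code{AcylACP}.
#'
#' @param AcylACP Acyl-ACP concentration(s), uM.
#' @param p A \code{ppgpp_parameters} object.
#' @return FA release rate(s), mg/l/OD/min, in [0, \code{V_tes}).
#' @export
v_fa <- function(AcylACP, p) {
  if (any(AcylACP < 0)) stop("negative Acyl-ACP")
  p$V_tes * AcylACP / (AcylACP + p$Km_tes)
}

#' Activity of the tandem rRNA P1/P2 promoter
#'
#' Hill inhibition of the tandem ribosomal promoter by ppGpp,
#' \eqn{1 / (1 + (ppGpp/Ki)^m)} with \eqn{m = 2} for the tandem
#' arrangement. Vectorised over \code{ppGpp}.
#'
#' @param ppGpp ppGpp concentration(s), uM.
#' @param p A \code{ppgpp_parameters} object.
#' @return Relative promoter activity in (0, 1].
#' @export
p1p2_activity <- function(ppGpp, p) {
  if (any(ppGpp < 0)) stop("negative ppGpp")
  1 / (1 + (ppGpp / p$Ki_P1P2_ppGpp)^p$m_hill)
}

#' Specific growth rate
#'
#' Growth requires the supporting nutrient \code{nutr}, ribosome activity,
#' and a minimal phospholipid-synthesis flux: \eqn{v_g = K_{gr} \cdot nutr
#' \cdot rib \cdot V_{PLS}/(V_{PLS} + V_0)}.
#'
#' @inheritParams v_fas
#' @return Specific growth rate, 1/min.
#' @export
growth_rate <- function(state, p) {
  V_PLS <- v_pls(state, p)
  nutr <- state[["nutr"]]
  if (nutr < 0) stop("negative state component")
  p$K_gr * nutr * state[["rib"]] * V_PLS / (V_PLS + p$V0)
}

#' Algebraic rates derived from a state
#'
#' Evaluates the five algebraic quantities of the model (FAS, PLS and FA
#' fluxes, P1/P2 promoter activity, specific growth rate) at one state or at
#' every row of a state matrix.
#'
#' @param state Named state vector, or a matrix with the state variables as
#'   columns.
#' @param p A \code{ppgpp_parameters} object.
#' @return A one-row data frame (or one row per input row) with columns
#'   \code{V_FAS}, \code{V_PLS}, \code{V_FA}, \code{P1P2}, \code{v_g}.
#' @export
derived_rates <- function(state, p) {
  if (is.matrix(state)) {
    AcylACP <- state[, "AcylACP"]; rib <- state[, "rib"]
    ppGpp <- state[, "ppGpp"]; nutr <- state[, "nutr"]
  } else {
    AcylACP <- state[["AcylACP"]]; rib <- state[["rib"]]
    ppGpp <- state[["ppGpp"]]; nutr <- state[["nutr"]]
  }
  ACP <- acp_free(AcylACP, p)
  V_FAS <- p$Vm_FAS * rib * ACP / (ACP + p$Km_ACP) *
    p$AcCoA_const / (p$AcCoA_const + p$Km_AcCoA) /
    (1 + AcylACP / p$Ki_AcylACP)
  V_PLS <- p$Vm_PLS * rib * AcylACP / (AcylACP + p$Km_AcylACP) /
    (1 + (ppGpp / p$Ki_ppGpp)^p$n_hill)
  V_FA <- p$V_tes * AcylACP / (AcylACP + p$Km_tes)
  P1P2 <- 1 / (1 + (ppGpp / p$Ki_P1P2_ppGpp)^p$m_hill)
  v_g <- p$K_gr * nutr * rib * V_PLS / (V_PLS + p$V0)
  data.frame(V_FAS = V_FAS, V_PLS = V_PLS, V_FA = V_FA,
             P1P2 = P1P2, v_g = v_g)
}

#' Right-hand side of the nine-ODE model
#'
#' Time derivative of the full state, in the \pkg{deSolve} function
#' signature. The Acyl-ACP balance is synthesis (FAS) minus consumption for
#' phospholipids (PLS) and free-FA release (Tes, converted to intracellular
#' units by \code{k_fa}); culture FA accumulates proportionally to cell
#' number; the two nutrients deplete proportionally to cell number with a
#' saturation floor that keeps them non-negative; ppGpp balances
#' ribosome-proportional synthesis against hydrolysis that requires both the
#' limiting nutrient (lim-dependent term) and Acyl-ACP; ribosome activity
#' relaxes towards P1/P2 promoter activity; the sensor cascade (I, GFP) is a
#' two-stage relay with first-order turnover.
#'
#' @param t Time, min (unused; the system is autonomous).
#' @param state Named state vector.
#' @param p A \code{ppgpp_parameters} object.
#' @param clamp_ppGpp If non-\code{NULL}, the ppGpp derivative is forced to
#'   zero (clamped-ppGpp experiments).
#' @return A list whose first element is the derivative vector, as required
#'   by \pkg{deSolve}.
#' @export
ppgpp_rhs <- function(t, state, p, clamp_ppGpp = NULL) {
  if (any(!is.finite(state)))
    stop("non-finite state during integration at t = ", t)
  AcylACP <- state[["AcylACP"]]; N <- state[["N"]]
  nutr <- state[["nutr"]]; lim <- state[["lim"]]
  ppGpp <- state[["ppGpp"]]; rib <- state[["rib"]]
  I <- state[["I"]]; GFP <- state[["GFP"]]

  ACP <- acp_free(AcylACP, p)
  V_FAS <- p$Vm_FAS * rib * ACP / (ACP + p$Km_ACP) *
    p$AcCoA_const / (p$AcCoA_const + p$Km_AcCoA) /
    (1 + AcylACP / p$Ki_AcylACP)
  V_PLS <- p$Vm_PLS * rib * AcylACP / (AcylACP + p$Km_AcylACP) /
    (1 + (ppGpp / p$Ki_ppGpp)^p$n_hill)
  V_FA <- p$V_tes * AcylACP / (AcylACP + p$Km_tes)
  P1P2 <- 1 / (1 + (ppGpp / p$Ki_P1P2_ppGpp)^p$m_hill)
  v_g <- p$K_gr * nutr * rib * V_PLS / (V_PLS + p$V0)
  fl <- p$depletion_floor

  d_ppGpp <- if (is.null(clamp_ppGpp)) {
    p$kp_ppGpp * rib -
      ppGpp * (p$km_ppGpp * lim + p$k0m_ppGpp) *
        AcylACP / (AcylACP + p$Km_Ac_pp)
  } else 0

  list(c(
    AcylACP = V_FAS - V_PLS - p$k_fa * V_FA,
    FA      = N * V_FA,
    N       = v_g * N,
    nutr    = -p$k_nutr * N * nutr / (nutr + fl),
    lim     = -p$k_lim * N * lim / (lim + fl),
    ppGpp   = d_ppGpp,
    rib     = p$kp_rib * P1P2 - p$km_rib * rib,
    I       = p$k_I * (P1P2 - I),
    GFP     = p$k_GFP * (1 / (1 + (I / p$Ki_I)^p$l_hill) - GFP)
  ))
}

core_names <- function() {
  c("AcylACP", "FA", "N", "nutr", "lim", "ppGpp", "rib")
}

## Right-hand side of the 7 upstream ("core") equations. The sensor cascade
## (I, GFP) never feeds back on these, so the simulator integrates it
## separately: core trajectories are then exactly independent of the sensor
## parameters, not merely independent up to solver roundoff.
core_rhs <- function(t, state, p, clamp_ppGpp = NULL) {
  if (any(!is.finite(state)))
    stop("non-finite state during integration at t = ", t)
  AcylACP <- state[["AcylACP"]]; N <- state[["N"]]
  nutr <- state[["nutr"]]; lim <- state[["lim"]]
  ppGpp <- state[["ppGpp"]]; rib <- state[["rib"]]

  ACP <- acp_free(AcylACP, p)
  V_FAS <- p$Vm_FAS * rib * ACP / (ACP + p$Km_ACP) *
    p$AcCoA_const / (p$AcCoA_const + p$Km_AcCoA) /
    (1 + AcylACP / p$Ki_AcylACP)
  V_PLS <- p$Vm_PLS * rib * AcylACP / (AcylACP + p$Km_AcylACP) /
    (1 + (ppGpp / p$Ki_ppGpp)^p$n_hill)
  V_FA <- p$V_tes * AcylACP / (AcylACP + p$Km_tes)
  P1P2 <- 1 / (1 + (ppGpp / p$Ki_P1P2_ppGpp)^p$m_hill)
  v_g <- p$K_gr * nutr * rib * V_PLS / (V_PLS + p$V0)
  fl <- p$depletion_floor

  d_ppGpp <- if (is.null(clamp_ppGpp)) {
    p$kp_ppGpp * rib -
      ppGpp * (p$km_ppGpp * lim + p$k0m_ppGpp) *
        AcylACP / (AcylACP + p$Km_Ac_pp)
  } else 0

  list(c(
    AcylACP = V_FAS - V_PLS - p$k_fa * V_FA,
    FA      = N * V_FA,
    N       = v_g * N,
    nutr    = -p$k_nutr * N * nutr / (nutr + fl),
    lim     = -p$k_lim * N * lim / (lim + fl),
    ppGpp   = d_ppGpp,
    rib     = p$kp_rib * P1P2 - p$km_rib * rib
  ))
}

## Sensor relay driven by a P1/P2 forcing function of time.
sensor_rhs <- function(t, state, p, p1p2_fun) {
  I <- state[["I"]]; GFP <- state[["GFP"]]
  P1P2 <- p1p2_fun(t)
  list(c(
    I   = p$k_I * (P1P2 - I),
    GFP = p$k_GFP * (1 / (1 + (I / p$Ki_I)^p$l_hill) - GFP)
  ))
}
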