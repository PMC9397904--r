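#' Species of the clock network
#'
#' Returns the canonical ordering of the 18 state variables: five mRNAs
#' (\code{m_wcc}, \code{m_frq}, \code{m_vvd}, \code{m_csp1}, \code{m_fam3}),
#' seven WCC/VVD protein species (dark-active \code{WCC}, phosphorylated
#' inactive \code{P_WCC}, light-activated monomer \code{WCCs}, homodimer
#' \code{WCC2s}, heterodimer \code{WCCVVDs}, dark \code{VVD}, light-activated
#' \code{VVDs}) and the six-pool FRQ maturation chain (\code{F1}\ldots\code{F5},
#' active complex \code{FFC}).
#'
#' @return Character vector of length 18.
#' @export
clockSpecies <- function() {
  c("m_wcc", "m_frq", "m_vvd", "m_csp1", "m_fam3",
    "WCC", "P_WCC", "WCCs", "WCC2s", "WCCVVDs", "VVD", "VVDs",
    "F1", "F2", "F3", "F4", "F5", "FFC")
}

#' Names of the kinetic parameters
#'
#' The 66 kinetic parameters of the model, in the canonical order used by the
#' compiled derivative. Units: rates are per hour, Michaelis and repression
#' constants are in arbitrary concentration units (a.u.), maximal transcription
#' rates in a.u. per hour, light-activation coefficients per hour per light
#' a.u.
#'
#' @return Character vector of length 66.
#' @export
clockParameterNames <- function() {
  c("bas_wcc", "vmax_l_wcc", "K_l_wcc",
    "bas_frq", "vmax_d_frq", "K_d_frq", "vmax_l_frq", "K_l_frq",
    "bas_vvd", "vmax_d_vvd", "K_d_vvd", "vmax_l_vvd", "K_l_vvd",
    "bas_csp1", "vmax_d_csp1", "K_d_csp1", "vmax_l_csp1", "K_l_csp1",
    "K_rep_csp1",
    "bas_fam3", "K_rep_fam3",
    "kdm_wcc", "kdm_frq", "kdm_vvd", "kdm_csp1", "kdm_fam3",
    "ktl_wcc", "ktl_frq", "ktl_vvd",
    paste0("kmat_", 1:5),
    paste0("kdf_", 1:5),
    "kdeg_ffc",
    "kcat_wcc", "KMp_wcc", "kcat_wccs", "KMp_wccs",
    "kcat_wcc2s", "KMp_wcc2s", "kcat_wccvvds", "KMp_wccvvds",
    "kd2",
    "klight_wcc", "klight_vvd",
    "krev_wccs", "krev_vvds", "krev_wcc2s", "krev_wccvvds",
    "kon_ww", "koff_ww", "kon_wv", "koff_wv",
    "kdeg_wcc", "kdeg_pwcc", "kdeg_wccs", "kdeg_wcc2s", "kdeg_wccvvds",
    "kdeg_vvd", "kdeg_vvds")
}

#' Parameters whose value is bounded below by the light-species half-time rule
#'
#' Degradation of every light-activated species (WCC*, the WCC* homodimer, the
#' WCC*VVD* heterodimer and VVD*) is constrained to a half-time of at most
#' 3 h, i.e. a rate of at least \code{log(2)/3} per hour.
#'
#' @return Named numeric vector of lower bounds.
#' @export
lightSpeciesDegradationBound <- function() {
  b <- log(2) / 3
  c(kdeg_wccs = b, kdeg_wcc2s = b, kdeg_wccvvds = b, kdeg_vvds = b)
}

#' Reaction table of the clock network
#'
#' A human-readable listing of all 46 elementary reactions: identifier,
#' reactants, products, rate law (an R expression in species names, parameter
#' names and the light intensity \code{u}) and a one-line description. The
#' same table drives the stoichiometry-matrix derivative oracle used for
#' cross-checking the compiled derivative, and can be written to disk with
#' \code{\link{writeReactionTable}}.
#'
#' @return A data.frame with columns \code{reaction}, \code{reactants},
#'   \code{products}, \code{rate}, \code{description}.
#' @export
reactionTable <- function() {
  rx <- .reactionList()
  fmt <- function(st, sign) {
    st <- st[sign(st) == sign]
    if (length(st) == 0L) return("-")
    paste(ifelse(abs(st) == 1, names(st), paste0(abs(st), " ", names(st))),
          collapse = " + ")
  }
  data.frame(
    reaction = vapply(rx, `[[`, "", "id"),
    reactants = vapply(rx, function(r) fmt(r$stoich, -1), ""),
    products = vapply(rx, function(r) fmt(r$stoich, +1), ""),
    rate = vapply(rx, `[[`, "", "rate"),
    description = vapply(rx, `[[`, "", "description"),
    stringsAsFactors = FALSE
  )
}

# internal reaction registry; stoich vectors are named sparse increments
.reactionList <- function() {
  r <- function(id, rate, stoich, description)
    list(id = id, rate = rate, stoich = stoich, description = description)
  list(
    r("tx_wcc", "bas_wcc + vmax_l_wcc * A_l / (K_l_wcc + A_l)",
      c(m_wcc = 1), "wcc transcription: constitutive TF plus light homodimer"),
    r("tx_frq",
      paste("bas_frq + vmax_d_frq * A_d / (K_d_frq + A_d) +",
            "vmax_l_frq * A_l / (K_l_frq + A_l)"),
      c(m_frq = 1), "frq transcription: WCC dark activity plus light homodimer"),
    r("tx_vvd",
      paste("bas_vvd + vmax_d_vvd * A_d / (K_d_vvd + A_d) +",
            "vmax_l_vvd * A_l / (K_l_vvd + A_l)"),
      c(m_vvd = 1), "vvd transcription: WCC dark activity plus light homodimer"),
    r("tx_csp1",
      paste("(bas_csp1 + vmax_d_csp1 * A_d / (K_d_csp1 + A_d) +",
            "vmax_l_csp1 * A_l / (K_l_csp1 + A_l)) /",
            "(1 + m_csp1 / K_rep_csp1)"),
      c(m_csp1 = 1), "csp-1 transcription with CSP-1 autorepression"),
    r("tx_fam3", "bas_fam3 / (1 + m_csp1 / K_rep_fam3)",
      c(m_fam3 = 1), "fam-3 transcription: constitutive, CSP-1 repressed"),
    r("dg_m_wcc", "kdm_wcc * m_wcc", c(m_wcc = -1), "wcc mRNA decay"),
    r("dg_m_frq", "kdm_frq * m_frq", c(m_frq = -1), "frq mRNA decay"),
    r("dg_m_vvd", "kdm_vvd * m_vvd", c(m_vvd = -1), "vvd mRNA decay"),
    r("dg_m_csp1", "kdm_csp1 * m_csp1", c(m_csp1 = -1), "csp-1 mRNA decay"),
    r("dg_m_fam3", "kdm_fam3 * m_fam3", c(m_fam3 = -1), "fam-3 mRNA decay"),
    r("tl_wcc", "ktl_wcc * m_wcc", c(WCC = 1),
      "WCC synthesis (translation and assembly as one step)"),
    r("tl_frq", "ktl_frq * m_frq", c(F1 = 1),
      "FRQ translation into the first maturation pool (chain step 1)"),
    r("tl_vvd", "ktl_vvd * m_vvd", c(VVD = 1), "VVD translation"),
    r("mat_1", "kmat_1 * F1", c(F1 = -1, F2 = 1), "maturation step 2"),
    r("mat_2", "kmat_2 * F2", c(F2 = -1, F3 = 1), "maturation step 3"),
    r("mat_3", "kmat_3 * F3", c(F3 = -1, F4 = 1), "maturation step 4"),
    r("mat_4", "kmat_4 * F4", c(F4 = -1, F5 = 1), "maturation step 5"),
    r("mat_5", "kmat_5 * F5", c(F5 = -1, FFC = 1),
      "maturation step 6: assembly of the active FFC"),
    r("dg_f1", "kdf_1 * F1", c(F1 = -1), "degradation of immature FRQ pool 1"),
    r("dg_f2", "kdf_2 * F2", c(F2 = -1), "degradation of immature FRQ pool 2"),
    r("dg_f3", "kdf_3 * F3", c(F3 = -1), "degradation of immature FRQ pool 3"),
    r("dg_f4", "kdf_4 * F4", c(F4 = -1), "degradation of immature FRQ pool 4"),
    r("dg_f5", "kdf_5 * F5", c(F5 = -1), "degradation of immature FRQ pool 5"),
    r("dg_ffc", "kdeg_ffc * FFC", c(FFC = -1),
      "FFC inactivation/degradation (single combined rate)"),
    r("ph_wcc", "kcat_wcc * FFC * WCC / (KMp_wcc + WCC)",
      c(WCC = -1, P_WCC = 1),
      "FFC-catalysed phosphorylation of dark WCC"),
    r("ph_wccs", "kcat_wccs * FFC * WCCs / (KMp_wccs + WCCs)",
      c(WCCs = -1, P_WCC = 1),
      "FFC-catalysed phosphorylation of WCC*"),
    r("ph_wcc2s", "kcat_wcc2s * FFC * WCC2s / (KMp_wcc2s + WCC2s)",
      c(WCC2s = -1, P_WCC = 2),
      "FFC-catalysed phosphorylation of the WCC* homodimer"),
    r("ph_wccvvds", "kcat_wccvvds * FFC * WCCVVDs / (KMp_wccvvds + WCCVVDs)",
      c(WCCVVDs = -1, P_WCC = 1, VVDs = 1),
      "FFC-catalysed phosphorylation of the heterodimer, releasing VVD*"),
    r("dephos", "kd2 * P_WCC", c(P_WCC = -1, WCC = 1),
      "dephosphorylation (reactivation) of P-WCC"),
    r("lact_wcc", "klight_wcc * u * WCC", c(WCC = -1, WCCs = 1),
      "light activation of WCC (photoadduct formation)"),
    r("lact_vvd", "klight_vvd * u * VVD", c(VVD = -1, VVDs = 1),
      "light activation of VVD"),
    r("rev_wccs", "krev_wccs * WCCs", c(WCCs = -1, WCC = 1),
      "spontaneous dark reversion of the WCC* photoadduct"),
    r("rev_vvds", "krev_vvds * VVDs", c(VVDs = -1, VVD = 1),
      "spontaneous dark reversion of the VVD* photoadduct"),
    r("rev_wcc2s", "krev_wcc2s * WCC2s", c(WCC2s = -1, WCCs = 1, WCC = 1),
      "photoadduct reversion within the homodimer (dimer falls apart)"),
    r("rev_wccvvds", "krev_wccvvds * WCCVVDs",
      c(WCCVVDs = -1, WCCs = 1, VVD = 1),
      "VVD* photoadduct reversion within the heterodimer"),
    r("dim_ww_on", "kon_ww * WCCs * WCCs", c(WCCs = -2, WCC2s = 1),
      "WCC* homodimerization"),
    r("dim_ww_off", "koff_ww * WCC2s", c(WCC2s = -1, WCCs = 2),
      "WCC* homodimer dissociation"),
    r("dim_wv_on", "kon_wv * WCCs * VVDs", c(WCCs = -1, VVDs = -1, WCCVVDs = 1),
      "WCC*-VVD* heterodimerization (photoadaptation)"),
    r("dim_wv_off", "koff_wv * WCCVVDs", c(WCCVVDs = -1, WCCs = 1, VVDs = 1),
      "heterodimer dissociation"),
    r("dg_wcc", "kdeg_wcc * WCC", c(WCC = -1), "dark WCC degradation (slow)"),
    r("dg_pwcc", "kdeg_pwcc * P_WCC", c(P_WCC = -1),
      "P-WCC degradation (slow; phosphorylated WCC is stable)"),
    r("dg_wccs", "kdeg_wccs * WCCs", c(WCCs = -1),
      "WCC* degradation (fast; half-time <= 3 h)"),
    r("dg_wcc2s", "kdeg_wcc2s * WCC2s", c(WCC2s = -1),
      "WCC* homodimer degradation (fast; half-time <= 3 h)"),
    r("dg_wccvvds", "kdeg_wccvvds * WCCVVDs", c(WCCVVDs = -1),
      "heterodimer degradation (VVD* stabilizes WCC*; half-time <= 3 h)"),
    r("dg_vvd", "kdeg_vvd * VVD", c(VVD = -1), "dark VVD degradation"),
    r("dg_vvds", "kdeg_vvds * VVDs", c(VVDs = -1),
      "VVD* degradation (fast; half-time <= 3 h)")
  )
}

#' Stoichiometry matrix of the reaction network
#'
#' @return Integer matrix, reactions in rows and the 18 species in columns.
#' @export
stoichiometryMatrix <- function() {
  rx <- .reactionList()
  sp <- clockSpecies()
  S <- matrix(0L, nrow = length(rx), ncol = length(sp),
              dimnames = list(vapply(rx, `[[`, "", "id"), sp))
  for (i in seq_along(rx)) S[i, names(rx[[i]]$stoich)] <- rx[[i]]$stoich
  S
}

# Independent derivative oracle: evaluates every reaction's rate-law string in
# an environment holding species, parameters and light, then assembles
# t(S) %*% flux. Deliberately slow and transparent; used only in tests and
# validation, never by the integrator.
.derivOracle <- function(state, params, light) {
  rx <- .reactionList()
  env <- as.list(c(state, params))
  env$u <- light
  env$A_d <- state[["WCC"]] + state[["WCCs"]] + state[["WCCVVDs"]]
  env$A_l <- state[["WCC2s"]]
  flux <- vapply(rx, function(r) eval(parse(text = r$rate), env), 0.0)
  drop(crossprod(stoichiometryMatrix(), flux))
}

#' Write the reaction table as delimited text
#'
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return Invisibly, the path.
#' @export
writeReactionTable <- function(path, sep = "\t") {
  utils::write.table(reactionTable(), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
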