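#' Build the Nrf2 pathway reaction network
#'
#' Constructs the reaction network of the Nrf2-Keap1-p62 model in one of
#' two mechanistic variants that differ only in how electrophilic stress
#' acts on the latch-bound Keap1-Nrf2 complex:
#'
#' * `"hinge_latch"`: modification of Keap1 converts the double-bound
#'   complex `K1N2_latch` into `K1N2_mod`, still bound at the ETGE motif.
#'   The complex persists but no longer routes Nrf2 to the proteasome, so
#'   only newly synthesised Nrf2 reaches the nucleus.
#' * `"dissociation"`: modification releases Nrf2 from the complex (the
#'   modified Keap1 leaves the latch-competent pool and is turned over),
#'   so pre-existing Nrf2 also becomes available for translocation.
#'
#' The shared backbone: basal synthesis of Nrf2, Keap1 and p62 with
#' additional mRNA-driven translation of Keap1, p62 and Srxn1; reversible
#' Keap1+Nrf2 association into the latch complex and proteasomal Nrf2
#' degradation with Keap1 recycling; p62-mediated routing of Keap1 to the
#' autophagosomal pool and its clearance; nuclear import/export of Nrf2;
#' Hill-type transcription of KEAP1, SQSTM1 and SRXN1 mRNA and of GSH
#' synthesis driven by nuclear Nrf2; constitutive NFE2L2 transcription;
#' electrophile (Stress) input, clearance, GSH conjugation and modification
#' of free Keap1; first-order turnover of every species.
#'
#' @param variant `"hinge_latch"` or `"dissociation"`.
#' @return An object of class `nrf2_network`: the reaction table
#'   (`$reactions`), species names (`$species`), stoichiometry matrix
#'   (`$S`, species x reactions) and precompiled rate-law indices.
#' @export
build_model <- function(variant = c("hinge_latch", "dissociation")) {
  variant <- match.arg(variant)
  sp <- species_names()

  rx <- function(name, reactants, products, law, ...) {
    c(list(name = name, reactants = reactants, products = products,
           law = law), list(...))
  }
  hill_rx <- function(name, product, basal, vmax, km, h)
    rx(name, "", product, "hill", basal = basal, vmax = vmax, km = km,
       hill = h, modifier = "nNrf2")

  reactions <- list(
    rx("prod_Nrf2",   "",               "Nrf2",          "mass_action", rate = "p_Nrf2"),
    rx("prod_Keap1",  "",               "Keap1",         "mass_action", rate = "p_Keap1"),
    rx("transl_Keap1","mKEAP1",         "mKEAP1 + Keap1","mass_action", rate = "kt_Keap1"),
    rx("prod_p62",    "",               "p62",           "mass_action", rate = "p_p62"),
    rx("transl_p62",  "mSQSTM1",        "mSQSTM1 + p62", "mass_action", rate = "kt_p62"),
    rx("bind_KN",     "Keap1 + Nrf2",   "K1N2_latch",    "mass_action", rate = "ka_KN"),
    rx("unbind_KN",   "K1N2_latch",     "Keap1 + Nrf2",  "mass_action", rate = "kd_KN"),
    rx("deg_Nrf2_proteasome", "K1N2_latch", "Keap1",     "mass_action", rate = "kdeg_Nrf2c"),
    rx("bind_Kp62",   "Keap1 + p62",    "K1p62",         "mass_action", rate = "ka_Kp62"),
    rx("auto_flux",   "K1p62",          "Keap1_auto",    "mass_action", rate = "k_auto"),
    rx("auto_clear",  "Keap1_auto",     "",              "mass_action", rate = "k_clear_auto"),
    rx("nrf2_import", "Nrf2",           "nNrf2",         "mass_action", rate = "k_in"),
    rx("nrf2_export", "nNrf2",          "Nrf2",          "mass_action", rate = "k_out"),
    hill_rx("tx_mKEAP1",  "mKEAP1",  "b_mKEAP1",  "V_mKEAP1",     "K_mKEAP1",  "h_mKEAP1"),
    rx("tx_mNFE2L2",  "",              "mNFE2L2",        "mass_action", rate = "b_mNFE2L2"),
    hill_rx("tx_mSQSTM1", "mSQSTM1", "b_mSQSTM1", "V_mSQSTM1",    "K_mSQSTM1", "h_mSQSTM1"),
    hill_rx("tx_mSRXN1",  "mSRXN1",  "b_mSRXN1",  "V_mSRXN1_eff", "K_mSRXN1",  "h_mSRXN1"),
    rx("transl_Srxn1","mSRXN1",        "mSRXN1 + Srxn1", "mass_action", rate = "kt_Srxn1"),
    hill_rx("gsh_synth",  "GSH",     "b_GSH",     "V_GSH",        "K_GSH",     "h_GSH"),
    rx("gsh_conjugation", "GSH + Stress", "",            "mass_action", rate = "k_conj"),
    rx("stress_input","",              "Stress",         "input"),
    rx("stress_clear","Stress",        "",               "mass_action", rate = "k_clear_stress_eff"),
    rx("mod_free_Keap1", "Stress + Keap1", "",           "mass_action", rate = "k_mod_free_eff"),
    if (variant == "hinge_latch")
      rx("mod_complex", "Stress + K1N2_latch", "K1N2_mod", "mass_action", rate = "k_mod_cplx_eff")
    else
      rx("mod_complex", "Stress + K1N2_latch", "Nrf2",     "mass_action", rate = "k_mod_cplx_eff"),
    rx("deg_Nrf2",    "Nrf2",       "", "mass_action", rate = "d_Nrf2"),
    rx("deg_Keap1",   "Keap1",      "", "mass_action", rate = "d_Keap1"),
    rx("deg_p62",     "p62",        "", "mass_action", rate = "d_p62"),
    rx("deg_latch",   "K1N2_latch", "", "mass_action", rate = "d_cplx"),
    rx("deg_mod",     "K1N2_mod",   "", "mass_action", rate = "d_cplx"),
    rx("deg_K1p62",   "K1p62",      "", "mass_action", rate = "d_cplx"),
    rx("deg_nNrf2",   "nNrf2",      "", "mass_action", rate = "d_nNrf2"),
    rx("deg_mKEAP1",  "mKEAP1",     "", "mass_action", rate = "d_mKEAP1"),
    rx("deg_mNFE2L2", "mNFE2L2",    "", "mass_action", rate = "d_mNFE2L2"),
    rx("deg_mSQSTM1", "mSQSTM1",    "", "mass_action", rate = "d_mSQSTM1"),
    rx("deg_mSRXN1",  "mSRXN1",     "", "mass_action", rate = "d_mSRXN1"),
    rx("deg_Srxn1",   "Srxn1",      "", "mass_action", rate = "d_Srxn1_eff"),
    rx("deg_GSH",     "GSH",        "", "mass_action", rate = "d_GSH")
  )
  compile_network(reactions, sp, variant)
}

# Parse "A + B" side strings into species index vectors.
.parse_side <- function(s, species) {
  s <- trimws(s)
  if (!nzchar(s)) return(integer(0))
  parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  idx <- match(parts, species)
  if (anyNA(idx)) stop("unknown species in reaction side: ", s)
  idx
}

# Compile a reaction list into stoichiometry + vectorised rate-law indices.
# Mass-action rates are k * prod(reactant concentrations); an index of
# n_species + 1 points at a padded constant 1 (absent second reactant or
# zeroth-order synthesis).
compile_network <- function(reactions, species, variant) {
  n_sp <- length(species)
  n_rx <- length(reactions)
  S <- matrix(0L, n_sp, n_rx, dimnames = list(species, NULL))
  law <- character(n_rx)
  ma_rate <- character(n_rx); ma_r1 <- rep(n_sp + 1L, n_rx)
  ma_r2 <- rep(n_sp + 1L, n_rx)
  hill <- list()
  input_idx <- integer(0)
  for (j in seq_len(n_rx)) {
    r <- reactions[[j]]
    law[j] <- r$law
    re <- .parse_side(r$reactants, species)
    pr <- .parse_side(r$products, species)
    for (i in re) S[i, j] <- S[i, j] - 1L
    for (i in pr) S[i, j] <- S[i, j] + 1L
    if (r$law == "mass_action") {
      if (length(re) > 2) stop("at most bimolecular mass action supported")
      ma_rate[j] <- r$rate
      if (length(re) >= 1) ma_r1[j] <- re[1]
      if (length(re) == 2) ma_r2[j] <- re[2]
    } else if (r$law == "hill") {
      hill[[length(hill) + 1L]] <- list(
        j = j, basal = r$basal, vmax = r$vmax, km = r$km, hill = r$hill,
        mod = match(r$modifier, species))
    } else if (r$law != "input") stop("unknown rate law: ", r$law)
    if (r$law == "input") input_idx <- c(input_idx, j)
  }
  tab <- data.frame(
    name = vapply(reactions, `[[`, "", "name"),
    reactants = vapply(reactions, `[[`, "", "reactants"),
    products = vapply(reactions, `[[`, "", "products"),
    law = law,
    parameters = vapply(reactions, function(r) {
      if (r$law == "mass_action") r$rate
      else if (r$law == "hill")
        paste(r$basal, r$vmax, r$km, r$hill, sep = ",")
      else "stimulus"
    }, ""),
    stringsAsFactors = FALSE)
  colnames(S) <- tab$name
  structure(list(variant = variant, species = species, reactions = tab,
                 S = S, law = law, ma = which(law == "mass_action"),
                 ma_rate = ma_rate, ma_r1 = ma_r1, ma_r2 = ma_r2,
                 hill = hill, input = input_idx),
            class = "nrf2_network")
}

#' @export
print.nrf2_network <- function(x, ...) {
  cat("Nrf2 pathway reaction network (variant: ", x$variant, ")\n",
      length(x$species), " species, ", nrow(x$reactions), " reactions\n",
      sep = "")
  invisible(x)
}

#' Write / read a reaction table
#'
#' The network is serialised as a plain TSV reaction list (name, reactants,
#' products, rate-law kind, parameter names), an SBML-compatible flat
#' representation that documents the model structure.
#'
#' @param network An `nrf2_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(network, path) {
  utils::write.table(network$reactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Build the numeric right-hand-side closure for one condition: parameters
# are frozen into numeric vectors so the inner function does no name lookup.
make_rhs <- function(network, params_resolved, input_fun = NULL) {
  n_sp <- length(network$species)
  S <- network$S
  ma <- network$ma
  k_ma <- unname(params_resolved[network$ma_rate[ma]])
  if (anyNA(k_ma)) stop("unresolved rate parameter in network")
  r1 <- network$ma_r1[ma]; r2 <- network$ma_r2[ma]
  hl <- network$hill
  h_j   <- vapply(hl, `[[`, 0L, "j")
  h_b   <- unname(params_resolved[vapply(hl, `[[`, "", "basal")])
  h_v   <- unname(params_resolved[vapply(hl, `[[`, "", "vmax")])
  h_km  <- unname(params_resolved[vapply(hl, `[[`, "", "km")])
  h_n   <- unname(params_resolved[vapply(hl, `[[`, "", "hill")])
  h_mod <- vapply(hl, `[[`, 0L, "mod")
  inp <- network$input
  n_rx <- ncol(S)
  if (is.null(input_fun)) input_fun <- function(t) 0
  function(t, y, parms) {
    x <- c(pmax(y, 0), 1)
    v <- numeric(n_rx)
    v[ma] <- k_ma * x[r1] * x[r2]
    if (length(h_j)) {
      xm <- x[h_mod]^h_n
      v[h_j] <- h_b + h_v * xm / (h_km^h_n + xm)
    }
    if (length(inp)) v[inp] <- input_fun(t)
    list(as.vector(S %*% v))
  }
}

#' Evaluate the model right-hand side
#'
#' Assembles the derivative vector d(state)/dt from the reaction network at
#' a given state and time, including the treatment input.
#'
#' @param state Named or unnamed non-negative state vector (length 15, model
#'   order).
#' @param t Time in hours.
#' @param params Named parameter vector.
#' @param stimulus A [stimulus()] specification (or `NULL` for no input).
#' @param variant Model variant tag.
#' @return Numeric derivative vector (a.u./h), named by species.
#' @export
ode_rhs <- function(state, t, params, stimulus = NULL,
                    variant = c("hinge_latch", "dissociation")) {
  variant <- match.arg(variant)
  if (!all(is.finite(state)) || !all(is.finite(params)))
    stop("non-finite state or parameters")
  net <- build_model(variant)
  compound <- if (is.null(stimulus)) "DEM" else stimulus$compound
  pr <- resolve_params(params, compound)
  input_fun <- if (is.null(stimulus)) NULL else
    function(tt) stimulus_value(tt, stimulus, bg = unname(params["dmso_bg"]))
  f <- make_rhs(net, pr, input_fun)
  out <- f(t, as.numeric(state), NULL)[[1]]
  names(out) <- net$species
  out
}
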