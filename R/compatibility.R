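# Flory-Huggins drug-polymer compatibility screening.

#' Screen configuration
#'
#' Collects the knobs of the compatibility screen so every report can embed
#' the exact configuration it was produced under.
#'
#' @param temperature absolute temperature in K (default 298.15).
#' @param delta_mode `"total"` (default): chi from the difference of the
#'   total solubility parameters (classical Hildebrand-Scatchard);
#'   `"hansen_weighted"`: chi from the squared factor-4 Hansen distance,
#'   for sensitivity runs.
#' @param polar_sum polar summation passed to [hsp_from_groups()].
#' @param total_sum total-parameter form passed to [hsp_from_groups()].
#' @param gas_constant R in J/(mol K). With delta^2 in MPa = J/cm^3 and V
#'   in cm^3/mol, chi = V (d_drug - d_poly)^2 / (R T) is dimensionless.
#' @return a `screen_config` list.
#' @export
screen_config <- function(temperature = 298.15,
                          delta_mode = c("total", "hansen_weighted"),
                          polar_sum = c("linear", "rss"),
                          total_sum = c("rss", "arithmetic"),
                          gas_constant = 8.314) {
  delta_mode <- match.arg(delta_mode)
  polar_sum <- match.arg(polar_sum)
  total_sum <- match.arg(total_sum)
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be > 0 K", call. = FALSE)
  }
  structure(list(temperature = temperature, delta_mode = delta_mode,
                 polar_sum = polar_sum, total_sum = total_sum,
                 gas_constant = gas_constant),
            class = "screen_config")
}

#' Flory-Huggins interaction parameter from HSP profiles
#'
#' Hildebrand-Scatchard estimate
#' `chi = V_drug * (delta_drug - delta_polymer)^2 / (R T)` with the drug's
#' molar volume (never the repeat unit's) and, by default, the total
#' solubility parameters. With `delta_mode = "hansen_weighted"` the squared
#' delta difference is replaced by the squared factor-4 Hansen distance.
#'
#' @param drug `hsp_profile` of the drug; its `V` must be present.
#' @param polymer `hsp_profile` of the polymer repeat unit.
#' @param config a [screen_config()].
#' @return dimensionless chi >= 0.
#' @export
flory_huggins_chi <- function(drug, polymer, config = screen_config()) {
  stopifnot(inherits(drug, "hsp_profile"), inherits(polymer, "hsp_profile"))
  if (is.null(drug$V) || !is.finite(drug$V) || drug$V <= 0) {
    stop("drug profile must carry a positive molar volume V", call. = FALSE)
  }
  dsq <- if (config$delta_mode == "total") {
    (drug$delta_total - polymer$delta_total)^2
  } else {
    hansen_distance(drug, polymer, weighted = TRUE)^2
  }
  drug$V * dsq / (config$gas_constant * config$temperature)
}

#' Rank candidate polymers for a drug by ascending chi
#'
#' Resolves every species to an HSP profile (explicit decompositions take
#' priority over structures), computes chi for each drug-polymer pair, and
#' ranks candidates from most (rank 1, lowest chi) to least compatible.
#' Ties are broken by ascending unweighted Hansen distance, then lexical
#' polymer id, so the ordering is deterministic under input permutation.
#'
#' @param drug a [molecule_spec()] for the drug.
#' @param polymers list of [molecule_spec()] for the candidate repeat
#'   units/blocks.
#' @param table a group table.
#' @param config a [screen_config()].
#' @return data.frame with columns
#'   `drug_id,polymer_id,delta_diff,chi,hansen_dist,rank`, sorted by rank.
#' @export
rank_candidates <- function(drug, polymers, table = load_group_table(),
                            config = screen_config()) {
  if (length(polymers) == 0L) {
    stop("empty candidate set: no polymers to rank", call. = FALSE)
  }
  if (inherits(polymers, "molecule_spec")) polymers <- list(polymers)
  dprof <- hsp_from_groups(decompose(drug, table), table,
                           polar_sum = config$polar_sum,
                           total_sum = config$total_sum)
  rows <- lapply(polymers, function(p) {
    pprof <- hsp_from_groups(decompose(p, table), table,
                             polar_sum = config$polar_sum,
                             total_sum = config$total_sum)
    data.frame(
      drug_id = drug$id, polymer_id = p$id,
      delta_diff = abs(dprof$delta_total - pprof$delta_total),
      chi = flory_huggins_chi(dprof, pprof, config),
      hansen_dist = hansen_distance(dprof, pprof, weighted = FALSE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$chi, out$hansen_dist, out$polymer_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Kendall rank agreement between a predicted and an observed order
#'
#' `tau = (concordant - discordant) / (n (n - 1) / 2)` computed by explicit
#' enumeration of all item pairs. +1 means identical orders, -1 exactly
#' reversed. Both orders must contain the same ids, each exactly once,
#' n >= 2.
#'
#' @param predicted character vector of ids in predicted order.
#' @param observed character vector of the same ids in observed order.
#' @return Kendall tau in [-1, 1].
#' @export
#' @examples
#' rank_agreement(c("a", "b", "c"), c("c", "b", "a")) # -1
rank_agreement <- function(predicted, observed) {
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  n <- length(predicted)
  if (n < 2L) stop("need at least two items to compare orders", call. = FALSE)
  if (anyDuplicated(predicted) || anyDuplicated(observed) ||
      !setequal(predicted, observed) || length(observed) != n) {
    stop("predicted and observed must be permutations of the same id set",
         call. = FALSE)
  }
  pos_pred <- match(predicted, predicted)          # 1..n by construction
  pos_obs <- match(predicted, observed)
  concordant <- 0L; discordant <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- sign(pos_pred[i] - pos_pred[j]) * sign(pos_obs[i] - pos_obs[j])
      if (s > 0) concordant <- concordant + 1L else discordant <- discordant + 1L
    }
  }
  (concordant - discordant) / (n * (n - 1L) / 2)
}
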