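# Orchestration: the screen and formulation-report pipelines used by the
# analysis scripts, plus the built-in molecule set of the BT44 / POx study.

#' Built-in molecule specifications of the BT44-POx screen
#'
#' The RET-agonist BT44 (C28H27F4N3O4S, a sulfonamide/arylamide with a
#' tetrahydroisoquinoline, a methoxyphenyl-piperazine and a
#' fluoro(trifluoromethyl)phenyl moiety) and the repeat units of the
#' poly(2-oxazoline) blocks pMeOx, pPrOx, pBuOx and pPentOx
#' (2-R-2-oxazoline with R = methyl, n-propyl, n-butyl, n-pentyl).
#'
#' BT44 carries both its SMILES structure and the curated group
#' decomposition (aromatic carbons as `CH_arom`/`C_arom` with one ring
#' closure per ring); the two routes agree, which is asserted in the test
#' suite. Repeat units are open-valence fragments, so they are specified
#' as explicit group counts: backbone `N-CH2-CH2` plus the acyl side chain
#' (`CO` + alkyl).
#'
#' @return named list of [molecule_spec()]: `BT44`, `pMeOx`, `pPrOx`,
#'   `pBuOx`, `pPentOx`.
#' @export
pox_screen_molecules <- function() {
  bt44 <- molecule_spec(
    "BT44", "drug",
    structure = "O=C(c1ccc(F)cc1C(F)(F)F)N1CCN(c2cc(S(=O)(=O)N3CCc4ccccc4C3)ccc2OC)CC1",
    formula = "C28H27F4N3O4S",
    counts = c(CH3 = 1, CH2 = 7, CH_arom = 10, C_arom = 8, C = 1, N = 3,
               O = 1, CO = 1, SO2 = 1, F = 4, ring_5plus = 5))
  unit <- function(id, n_ch2, formula) {
    molecule_spec(id, "polymer_repeat_unit", formula = formula,
                  counts = c(CH3 = 1, CH2 = n_ch2, CO = 1, N = 1))
  }
  list(BT44 = bt44,
       pMeOx = unit("pMeOx", 2, "C4H7NO"),
       pPrOx = unit("pPrOx", 4, "C6H11NO"),
       pBuOx = unit("pBuOx", 5, "C7H13NO"),
       pPentOx = unit("pPentOx", 6, "C8H15NO"))
}

#' Run the full compatibility screen and write its report files
#'
#' Decomposes every species, computes HSP profiles and Flory-Huggins chi
#' values, ranks the candidates, and writes `hsp_profiles.csv`,
#' `compatibility_screen.csv` and `screen_summary.json` (the latter embeds
#' the configuration, group-table version and package version) to
#' `out_dir`. Reruns with the same inputs produce byte-identical CSV
#' bodies.
#'
#' @param drug a [molecule_spec()].
#' @param polymers list of candidate [molecule_spec()]s.
#' @param table a group table.
#' @param config a [screen_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return list with `profiles` (data.frame), `screen` (ranked
#'   data.frame) and `summary` (list), invisibly written to disk.
#' @export
run_screen <- function(drug, polymers, table = load_group_table(),
                       config = screen_config(), out_dir = NULL) {
  if (length(polymers) == 0L) {
    stop("empty candidate set: no polymers to screen", call. = FALSE)
  }
  species <- c(list(drug), polymers)
  profiles <- hsp_table(lapply(species, function(s) {
    hsp_from_groups(decompose(s, table), table,
                    polar_sum = config$polar_sum,
                    total_sum = config$total_sum)
  }))
  screen <- rank_candidates(drug, polymers, table, config)
  summary <- list(
    drug_id = drug$id,
    rank_order = screen$polymer_id,
    chi = as.list(stats::setNames(screen$chi, screen$polymer_id)),
    config = unclass(config),
    group_table_version = attr(table, "version"),
    package_version = as.character(utils::packageVersion("hspcompat"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(profiles, file.path(out_dir, "hsp_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(out_dir, "compatibility_screen.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(profiles = profiles, screen = screen, summary = summary)
}

#' Turn a formulation measurement table into an LC/LE/stability report
#'
#' Computes loading capacity and efficiency per record (raw and
#' integer-rounded), summarizes each stability series (records sharing
#' polymer, drug and feeds across days), derives the observed solubilizer
#' order from the day-0 loading capacities, and, when a predicted order is
#' supplied, scores the prediction with [rank_agreement()].
#'
#' @param records data.frame of validated records (see
#'   [read_formulation_csv()]).
#' @param predicted_order optional character vector: polymer ids in
#'   predicted compatibility order (best first).
#' @param detection_threshold complete-precipitation threshold, g/L.
#' @param out_dir optional output directory for `formulation_report.csv`
#'   and `formulation_summary.json`.
#' @return list with `per_record`, `stability`, `observed_order`, and
#'   (when a prediction is given) `rank_agreement`.
#' @export
run_formulation_report <- function(records, predicted_order = NULL,
                                   detection_threshold = 0.01,
                                   out_dir = NULL) {
  per <- records
  per$lc <- loading_capacity(per$solubilized, per$polymer_feed)
  per$le <- loading_efficiency(per$solubilized, per$drug_feed)
  per$lc_rounded <- report_rounding(per$lc)
  per$le_rounded <- report_rounding(per$le)

  key <- interaction(per$polymer_id, per$drug_id, per$polymer_feed,
                     per$drug_feed, drop = TRUE)
  stab <- lapply(split(per, key), function(g) {
    if (nrow(g) < 2L || length(unique(g$day)) < 2L) return(NULL)
    g <- g[order(g$day), ]
    s <- stability_series(g[g$day == min(g$day), ][1, ], g$day, g$solubilized)
    smry <- stability_summary(s, detection_threshold)
    data.frame(polymer_id = g$polymer_id[1], drug_feed = g$drug_feed[1],
               polymer_feed = g$polymer_feed[1],
               lc_day0 = smry$lc_by_day$lc[1],
               lc_last = smry$lc_by_day$lc[nrow(smry$lc_by_day)],
               retention_fraction = smry$retention_fraction,
               time_to_complete_precipitation =
                 smry$time_to_complete_precipitation,
               stringsAsFactors = FALSE)
  })
  stab <- do.call(rbind, Filter(Negate(is.null), stab))
  if (!is.null(stab)) rownames(stab) <- NULL

  day0 <- per[per$day == 0, ]
  best_lc <- tapply(day0$lc, day0$polymer_id, max)
  observed_order <- names(sort(best_lc, decreasing = TRUE))
  out <- list(per_record = per, stability = stab,
              observed_order = observed_order)
  if (!is.null(predicted_order)) {
    out$rank_agreement <- rank_agreement(predicted_order, observed_order)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per, file.path(out_dir, "formulation_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(observed_order = observed_order,
           rank_agreement = out$rank_agreement,
           stability = stab,
           detection_threshold_gL = detection_threshold,
           package_version =
             as.character(utils::packageVersion("hspcompat"))),
      file.path(out_dir, "formulation_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }
  out
}
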