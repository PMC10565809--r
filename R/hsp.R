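# Hansen solubility parameters from group contributions.

#' Fedors molar volume of a decomposed molecule
#'
#' Sums the Fedors volume increments over a group-count vector:
#' V = sum(count_i * V_fedors_i), in cm^3/mol. Ring-closure correction
#' entries contribute like any other row; the result must be positive.
#'
#' @param decomp a [decompose()] result (or a named count vector).
#' @param table a group table.
#' @return molar volume, cm^3/mol.
#' @export
fedors_molar_volume <- function(decomp, table = load_group_table()) {
  counts <- decomposition_counts(decomp)
  rows <- resolve_groups(counts, table)
  V <- sum(counts * rows$V_fedors)
  if (!is.finite(V) || V <= 0) {
    stop("non-positive Fedors molar volume (", round(V, 3),
         " cm^3/mol): correction entries overwhelm the group sum",
         call. = FALSE)
  }
  V
}

decomposition_counts <- function(decomp) {
  counts <- if (inherits(decomp, "group_decomposition")) decomp$counts
            else unlist(decomp)
  if (length(counts) == 0L || sum(counts) == 0) {
    stop("empty group decomposition", call. = FALSE)
  }
  counts
}

#' Hansen solubility parameter profile from group contributions
#'
#' Computes the dispersion, polar and hydrogen-bonding components from the
#' Hoftyzer-van Krevelen molar attraction constants:
#'
#' * `delta_d = sum(F_di) / V`
#' * `delta_p = sum(F_pi) / V` (default) or `sqrt(sum(F_pi^2)) / V` with
#'   `polar_sum = "rss"`
#' * `delta_h = sqrt(sum(E_hi) / V)`
#' * `delta_total = sqrt(delta_d^2 + delta_p^2 + delta_h^2)` (default) or
#'   the literal component sum with `total_sum = "arithmetic"`, kept for
#'   sensitivity analysis only.
#'
#' All deltas are in MPa^0.5 with V in cm^3/mol and E_hi in J/mol
#' (1 MPa = 1 J/cm^3, so the units close without conversion factors).
#' The choice of the linear polar summation as default and the orthodox
#' root-sum-of-squares as an option is discussed in the methods vignette.
#'
#' @param decomp a [decompose()] result or named count vector.
#' @param table a group table.
#' @param V molar volume in cm^3/mol; defaults to
#'   [fedors_molar_volume()] of the same decomposition.
#' @param polar_sum `"linear"` (default) or `"rss"`.
#' @param total_sum `"rss"` (default) or `"arithmetic"`.
#' @return an `hsp_profile`: list with `molecule_id`, `delta_d`, `delta_p`,
#'   `delta_h`, `delta_total`, `V`.
#' @export
#' @examples
#' tab <- load_group_table()
#' d <- decompose(molecule_spec("hexane", "drug", structure = "CCCCCC"), tab)
#' hsp_from_groups(d, tab)
hsp_from_groups <- function(decomp, table = load_group_table(), V = NULL,
                            polar_sum = c("linear", "rss"),
                            total_sum = c("rss", "arithmetic")) {
  polar_sum <- match.arg(polar_sum)
  total_sum <- match.arg(total_sum)
  counts <- decomposition_counts(decomp)
  rows <- resolve_groups(counts, table)
  if (is.null(V)) V <- fedors_molar_volume(counts, table)
  if (!is.finite(V) || V <= 0) stop("molar volume must be > 0", call. = FALSE)
  Fd <- sum(counts * rows$F_di)
  Eh <- sum(counts * rows$E_hi)
  if (Eh < 0) stop("negative hydrogen-bond energy sum", call. = FALSE)
  delta_d <- max(Fd / V, 0)
  delta_p <- if (polar_sum == "linear") {
    sum(counts * rows$F_pi) / V
  } else {
    sqrt(sum(counts * rows$F_pi^2)) / V
  }
  delta_h <- sqrt(Eh / V)
  delta_total <- if (total_sum == "rss") {
    sqrt(delta_d^2 + delta_p^2 + delta_h^2)
  } else {
    delta_d + delta_p + delta_h
  }
  structure(list(
    molecule_id = if (inherits(decomp, "group_decomposition"))
                    decomp$molecule_id else NA_character_,
    delta_d = delta_d, delta_p = delta_p, delta_h = delta_h,
    delta_total = delta_total, V = V
  ), class = "hsp_profile")
}

#' @export
print.hsp_profile <- function(x, ...) {
  cat(sprintf(
    "<hsp_profile> %s\n  dd=%.2f dp=%.2f dh=%.2f dtotal=%.2f MPa^0.5, V=%.1f cm^3/mol\n",
    x$molecule_id, x$delta_d, x$delta_p, x$delta_h, x$delta_total, x$V))
  invisible(x)
}

#' Distance between two molecules in Hansen space
#'
#' Unweighted (default): `sqrt(ddd^2 + ddp^2 + ddh^2)`, the plain Euclidean
#' distance between the two (delta_d, delta_p, delta_h) triples. Weighted
#' (`weighted = TRUE`): the conventional Hansen Ra with the factor 4 on the
#' dispersion term, `sqrt(4 ddd^2 + ddp^2 + ddh^2)`.
#'
#' @param a,b `hsp_profile` objects.
#' @param weighted apply the factor-4 Ra convention.
#' @return distance in MPa^0.5.
#' @export
hansen_distance <- function(a, b, weighted = FALSE) {
  stopifnot(inherits(a, "hsp_profile"), inherits(b, "hsp_profile"))
  wd <- if (weighted) 4 else 1
  sqrt(wd * (a$delta_d - b$delta_d)^2 + (a$delta_p - b$delta_p)^2 +
       (a$delta_h - b$delta_h)^2)
}

#' Convert solubility parameters from (cal/cm^3)^0.5 to MPa^0.5
#'
#' Legacy tables quote Hildebrand/Hansen parameters in (cal/cm^3)^0.5;
#' 1 (cal/cm^3)^0.5 = 2.0455 MPa^0.5.
#'
#' @param x value(s) in (cal/cm^3)^0.5.
#' @return value(s) in MPa^0.5.
#' @export
mpa_from_cal <- function(x) x * 2.0455

#' Export HSP profiles as a data frame
#'
#' @param profiles a list of `hsp_profile` objects.
#' @return data.frame with columns
#'   `molecule_id,delta_d,delta_p,delta_h,delta_total,V`.
#' @export
hsp_table <- function(profiles) {
  if (inherits(profiles, "hsp_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(molecule_id = p$molecule_id, delta_d = p$delta_d,
               delta_p = p$delta_p, delta_h = p$delta_h,
               delta_total = p$delta_total, V = p$V,
               stringsAsFactors = FALSE)
  }))
}
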