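# Molecule specifications: structure string, molecular formula, and/or an
# explicit functional-group decomposition.

#' Create a molecule specification
#'
#' A molecule enters the pipeline either as a structure string (SMILES-style
#' line notation, handed to the ChemmineR/OpenBabel parsing backend by
#' [decompose()]), as an explicit functional-group count vector, or both.
#' Explicit counts always take priority in [decompose()], so curated group
#' assignments can be encoded directly.
#'
#' @param id molecule identifier.
#' @param role one of `"drug"`, `"polymer_repeat_unit"`,
#'   `"homopolymer_block"`.
#' @param structure optional line-notation structure string.
#' @param formula optional molecular formula (Hill string, e.g.
#'   `"C28H27F4N3O4S"`), used for validation and molar mass.
#' @param counts optional named vector/list of group counts (an explicit
#'   decomposition).
#' @return an object of class `molecule_spec`.
#' @export
#' @examples
#' molecule_spec("hexane", "drug", structure = "CCCCCC", formula = "C6H14")
molecule_spec <- function(id, role = c("drug", "polymer_repeat_unit",
                                       "homopolymer_block"),
                          structure = NULL, formula = NULL, counts = NULL) {
  role <- match.arg(role)
  if (is.null(structure) && is.null(counts)) {
    stop("molecule '", id,
         "': at least one of `structure` or `counts` is required",
         call. = FALSE)
  }
  if (!is.null(counts)) {
    counts <- unlist(counts)
    if (length(counts) == 0L || any(counts < 0) ||
        any(counts != round(counts)) || sum(counts) == 0) {
      stop("molecule '", id,
           "': group counts must be non-negative integers, not all zero",
           call. = FALSE)
    }
    counts <- counts[counts > 0]
  }
  structure(list(id = id, role = role, structure = structure,
                 formula = formula, counts = counts),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat("<molecule_spec> ", x$id, " (", x$role, ")\n", sep = "")
  if (!is.null(x$formula)) cat("  formula:   ", x$formula, "\n", sep = "")
  if (!is.null(x$structure)) cat("  structure: ", x$structure, "\n", sep = "")
  if (!is.null(x$counts)) {
    cat("  groups:    ",
        paste(names(x$counts), x$counts, sep = ":", collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Parse a molecular formula string into element counts
#'
#' @param formula a formula string such as `"C8H13NO"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(pieces)) != nchar(formula)) {
    stop("malformed formula string: ", formula, call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", pieces)
  ns <- sub("^[A-Za-z]+", "", pieces)
  ns <- ifelse(nzchar(ns), as.integer(ns), 1L)
  counts <- tapply(ns, elements, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[hill_order(names(out))]
}

# Hill convention: C, then H, then everything else alphabetically
hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  intersect(c("C", "H", rest), elements)
}

format_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- hill_order(names(counts))
  paste0(els, ifelse(counts[els] > 1L, counts[els], ""), collapse = "")
}

# IUPAC 2021 conventional atomic weights (g/mol), fixed for determinism
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Br = 79.904, I = 126.904
)

#' Molar mass from a molecular formula
#'
#' Sums fixed IUPAC 2021 atomic weights over the element counts of a
#' molecule. Accepts a `molecule_spec` (using its `formula`, or the
#' elemental totals of its explicit decomposition if no formula is given),
#' a formula string, or a named element-count vector.
#'
#' @param x a `molecule_spec`, formula string, or named count vector.
#' @param table group table, needed only when the mass must be derived from
#'   an explicit decomposition.
#' @param digits optional decimal places for reporting (e.g. 2 for the
#'   conventional two-decimal presentation); `NULL` (default) returns the
#'   full-precision sum.
#' @return molar mass in g/mol.
#' @export
#' @examples
#' molar_mass("C28H27F4N3O4S", digits = 2) # 577.59
molar_mass <- function(x, table = NULL, digits = NULL) {
  counts <- element_counts(x, table)
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- sum(ATOMIC_WEIGHTS[names(counts)] * counts)
  if (is.null(digits)) m else round(m, digits)
}

element_counts <- function(x, table = NULL) {
  if (inherits(x, "molecule_spec")) {
    if (!is.null(x$formula)) return(parse_formula(x$formula))
    if (!is.null(x$counts)) {
      if (is.null(table)) table <- load_group_table()
      return(decomposition_elements(x$counts, table))
    }
    stop("molecule '", x$id, "' has neither formula nor explicit counts",
         call. = FALSE)
  }
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot derive element counts from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

# elemental totals implied by a group-count vector
decomposition_elements <- function(counts, table) {
  rows <- resolve_groups(counts, table)
  total <- integer(0)
  for (i in seq_along(counts)) {
    if (rows$is_correction[i] || !nzchar(rows$composition[i])) next
    el <- parse_formula(rows$composition[i]) * counts[[i]]
    for (e in names(el)) {
      total[e] <- (if (e %in% names(total)) total[[e]] else 0L) + el[[e]]
    }
  }
  total[hill_order(names(total))]
}
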