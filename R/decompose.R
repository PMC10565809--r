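# Decomposition of molecules into functional-group count vectors.
#
# Two routes: explicit curated counts (always take priority, validated
# against the group table and, when present, the molecular formula), or a
# rule-based atom classifier over the structure string parsed by the
# ChemmineR/OpenBabel backend.

#' Decompose a molecule into functional-group counts
#'
#' If the specification carries explicit group counts they are validated
#' and passed through unchanged. Otherwise the structure string is parsed
#' (SMILES-style notation via ChemmineR/OpenBabel) and every heavy atom is
#' assigned to exactly one group by a deterministic classifier with a
#' documented precedence: multi-atom groups are matched first, from most to
#' least specific (sulfonyl SO2, then carboxyl COOH, ester COO, carbonyl
#' CO, nitrile CN), then hydroxyl/ether oxygen, amine nitrogen by hydrogen
#' count, aromatic carbon (`CH_arom`/`C_arom`), alkene carbon, and finally
#' saturated carbon by hydrogen count (CH3/CH2/CH/C). One ring-closure
#' correction (`ring_5plus` or `ring_3_4`) is added per ring.
#'
#' When both a formula and a decomposition are available, their elemental
#' totals must agree; a mismatch is an error.
#'
#' @param spec a [molecule_spec()].
#' @param table a group table from [load_group_table()].
#' @return an object of class `group_decomposition`: list with
#'   `molecule_id`, `counts` (named integer vector), and `source`
#'   (`"explicit"` or `"parsed"`).
#' @export
#' @examples
#' tab <- load_group_table()
#' decompose(molecule_spec("hexane", "drug", structure = "CCCCCC"), tab)
decompose <- function(spec, table = load_group_table()) {
  stopifnot(inherits(spec, "molecule_spec"))
  if (!is.null(spec$counts)) {
    counts <- spec$counts
    resolve_groups(counts, table)
    source <- "explicit"
  } else {
    counts <- parse_structure_groups(spec$structure, table)
    source <- "parsed"
  }
  if (!is.null(spec$formula)) {
    got <- decomposition_elements(counts, table)
    want <- parse_formula(spec$formula)
    if (!identical(as.integer(want[hill_order(names(want))]),
                   as.integer(got[hill_order(names(got))])) ||
        !setequal(names(want), names(got))) {
      stop("molecule '", spec$id, "': decomposition elements (",
           format_formula(got), ") disagree with formula (",
           format_formula(want), ")", call. = FALSE)
    }
  }
  structure(list(molecule_id = spec$id, counts = counts, source = source),
            class = "group_decomposition")
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat("<group_decomposition> ", x$molecule_id, " [", x$source, "]\n  ",
      paste(names(x$counts), x$counts, sep = ":", collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# ---- structure parsing backend -------------------------------------------

# Parse a SMILES string into an atom/bond table via ChemmineR (OpenBabel).
# Implicit hydrogens are restored from a standard neutral valence model.
parse_structure_atoms <- function(structure) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(structure))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(element)
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.numeric(bb[, 3]))
  # order 4 encodes an un-kekulized aromatic bond
  bond_eq <- ifelse(bonds$order == 4, 1.5, bonds$order)
  valence_sum <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    valence_sum[bonds$i[k]] <- valence_sum[bonds$i[k]] + bond_eq[k]
    valence_sum[bonds$j[k]] <- valence_sum[bonds$j[k]] + bond_eq[k]
  }
  valence_sum <- round(valence_sum)
  std <- list(C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5),
              F = 1, Cl = 1, Br = 1, I = 1, B = 3, H = 1)
  hcount <- integer(n)
  for (a in seq_len(n)) {
    v <- std[[element[a]]]
    if (is.null(v)) {
      stop("unsupported element in structure: ", element[a], call. = FALSE)
    }
    target <- v[v >= valence_sum[a]][1]
    hcount[a] <- if (is.na(target)) 0L else as.integer(target - valence_sum[a])
  }
  list(element = element, bonds = bonds, hcount = hcount, n = n)
}

# Ring perception: smallest cycle through every cyclic bond, greedily
# reduced to a minimal cycle set of size = cyclomatic number.
perceive_rings <- function(mol) {
  n <- mol$n
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  shortest_cycle <- function(i, j) {
    # BFS from i to j avoiding the direct i-j edge
    dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
    dist[i] <- 0L; queue <- i
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == i && w == j) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; parent[w] <- v
          if (w == j) {
            path <- w
            while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
            return(path)
          }
          queue <- c(queue, w)
        }
      }
    }
    NULL
  }
  cycles <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    cyc <- shortest_cycle(mol$bonds$i[k], mol$bonds$j[k])
    if (!is.null(cyc)) cycles[[length(cycles) + 1L]] <- sort(cyc)
  }
  cycles <- unique(cycles)
  n_rings <- nrow(mol$bonds) - n + n_components(mol)
  if (n_rings <= 0L || length(cycles) == 0L) return(list())
  # smallest first, deterministic tie-break on member indices
  ord <- order(lengths(cycles), vapply(cycles, paste, "", collapse = ","))
  cycles <- cycles[ord]
  edge_key <- function(i, j) paste(min(i, j), max(i, j))
  covered <- character(0)
  chosen <- list()
  for (cyc in cycles) {
    ring_edges <- vapply(seq_along(cyc), function(t) {
      edge_key(cyc[t], cyc[t %% length(cyc) + 1L])
    }, "")
    # ring atoms are sorted, so reconstruct edges from adjacency instead
    ring_edges <- character(0)
    for (a in cyc) for (b in adj[[a]]) {
      if (b %in% cyc) ring_edges <- c(ring_edges, edge_key(a, b))
    }
    ring_edges <- unique(ring_edges)
    if (any(!(ring_edges %in% covered))) {
      chosen[[length(chosen) + 1L]] <- cyc
      covered <- union(covered, ring_edges)
    }
    if (length(chosen) == n_rings) break
  }
  chosen
}

n_components <- function(mol) {
  seen <- rep(FALSE, mol$n)
  adj <- vector("list", mol$n)
  for (k in seq_len(nrow(mol$bonds))) {
    adj[[mol$bonds$i[k]]] <- c(adj[[mol$bonds$i[k]]], mol$bonds$j[k])
    adj[[mol$bonds$j[k]]] <- c(adj[[mol$bonds$j[k]]], mol$bonds$i[k])
  }
  comp <- 0L
  for (s in seq_len(mol$n)) {
    if (seen[s]) next
    comp <- comp + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
  }
  comp
}

# classify every heavy atom into exactly one functional group
parse_structure_groups <- function(structure, table) {
  mol <- parse_structure_atoms(structure)
  rings <- perceive_rings(mol)
  b <- mol$bonds
  neighbors <- function(a) {
    rbind(data.frame(other = b$j[b$i == a], order = b$order[b$i == a]),
          data.frame(other = b$i[b$j == a], order = b$order[b$j == a]))
  }
  # aromatic: member of a 5/6-ring in which every atom carries an in-ring
  # double (or aromatic) bond
  aromatic <- rep(FALSE, mol$n)
  for (cyc in rings) {
    if (!(length(cyc) %in% c(5L, 6L))) next
    ok <- all(vapply(cyc, function(a) {
      nb <- neighbors(a)
      any(nb$other %in% cyc & nb$order %in% c(2, 4))
    }, TRUE))
    if (ok) aromatic[cyc] <- TRUE
  }
  assigned <- rep(NA_character_, mol$n)   # group label per atom
  consumed <- rep(FALSE, mol$n)           # atom absorbed into another group
  add <- function(counts, key) {
    counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) + 1L
    counts
  }
  counts <- integer(0)
  el <- mol$element; hc <- mol$hcount
  # pass 1: multi-atom groups, most specific first
  for (a in which(el == "S")) {
    nb <- neighbors(a)
    o2 <- nb$other[nb$order == 2 & el[nb$other] == "O"]
    if (length(o2) >= 2L) {
      counts <- add(counts, "SO2")
      assigned[a] <- "SO2"; consumed[o2[1:2]] <- TRUE
    }
  }
  for (a in which(el == "C" & !consumed)) {
    nb <- neighbors(a)
    odbl <- nb$other[nb$order == 2 & el[nb$other] == "O" & !consumed[nb$other]]
    if (length(odbl) == 0L) next
    osng <- nb$other[nb$order == 1 & el[nb$other] == "O" & !consumed[nb$other]]
    if (length(osng) >= 1L && hc[osng[1]] >= 1L) {
      counts <- add(counts, "COOH")
      assigned[a] <- "COOH"; consumed[c(odbl[1], osng[1])] <- TRUE
    } else if (length(osng) >= 1L) {
      counts <- add(counts, "COO")
      assigned[a] <- "COO"; consumed[c(odbl[1], osng[1])] <- TRUE
    } else {
      counts <- add(counts, "CO")
      assigned[a] <- "CO"; consumed[odbl[1]] <- TRUE
    }
  }
  for (a in which(el == "C" & is.na(assigned) & !consumed)) {
    nb <- neighbors(a)
    ntrp <- nb$other[nb$order == 3 & el[nb$other] == "N" & !consumed[nb$other]]
    if (length(ntrp) >= 1L) {
      counts <- add(counts, "CN")
      assigned[a] <- "CN"; consumed[ntrp[1]] <- TRUE
    }
  }
  # pass 2: single-atom groups
  for (a in seq_len(mol$n)) {
    if (consumed[a] || !is.na(assigned[a])) next
    key <- switch(el[a],
      O = if (hc[a] >= 1L) "OH" else "O",
      N = c("N", "NH", "NH2")[min(hc[a], 2L) + 1L],
      F = "F", Cl = "Cl", S = "S",
      C = {
        if (aromatic[a]) {
          if (hc[a] >= 1L) "CH_arom" else "C_arom"
        } else {
          nb <- neighbors(a)
          if (any(nb$order == 2)) {
            c("=C<", "=CH-", "CH2=")[min(hc[a], 2L) + 1L]
          } else {
            c("C", "CH", "CH2", "CH3")[min(hc[a], 3L) + 1L]
          }
        }
      },
      NA_character_
    )
    if (is.na(key)) {
      stop("unmatched substructure: atom ", el[a], "_", a,
           " could not be assigned to any group", call. = FALSE)
    }
    counts <- add(counts, key)
    assigned[a] <- key
  }
  uncovered <- which(is.na(assigned) & !consumed)
  if (length(uncovered) > 0L) {
    stop("unmatched substructure: atoms ",
         paste0(el[uncovered], "_", uncovered, collapse = ", "),
         call. = FALSE)
  }
  for (cyc in rings) {
    counts <- add(counts, if (length(cyc) <= 4L) "ring_3_4" else "ring_5plus")
  }
  resolve_groups(counts, table)
  counts
}
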