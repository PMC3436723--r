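#' @useDynLib nplikeness, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import dplyr
#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Default valences used to fill open positions with implicit hydrogens.
# S/Se and P/As are multi-valent (sulfones, phosphates); the smallest
# valence that accommodates the bond-order sum is used. Charge shifts the
# valence of lone-pair bearers (N+ -> 4, O- -> 1, ...); carbon loses one
# position per unit of charge of either sign.
.npl_valence <- list(
  C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6), F = 1, Cl = 1, Br = 1,
  I = 1, As = c(3, 5), Se = c(2, 4, 6), B = 3, H = 1
)

#' Construct a molecule record
#'
#' A molecule is a labelled graph: heavy atoms (element, formal charge,
#' implicit-hydrogen count, aromatic flag) joined by bonds of integer order
#' 1-3, with an aromatic flag on bonds that belong to an aromatic ring.
#' Hydrogens are always implicit. Atom indices are 1-based and stable for the
#' lifetime of the record.
#'
#' @param element character vector of element symbols.
#' @param charge integer vector of formal charges (default all 0).
#' @param bonds data frame with columns `a`, `b` (atom indices) and `order`
#'   (1, 2 or 3), or NULL for a bond-less molecule.
#' @param uuid identifier shared by all fragments split from one parent.
#' @param name optional source title.
#' @param origin optional source annotation (file and record number).
#' @param perceive if TRUE (default), implicit hydrogen counts and
#'   aromaticity are (re)derived from the graph.
#' @return an object of class `npl_mol`.
#' @export
npl_mol <- function(element, charge = NULL, bonds = NULL, uuid = NA_character_,
                    name = NA_character_, origin = NA_character_,
                    perceive = TRUE) {
  n <- length(element)
  charge <- as.integer(charge %||% rep(0L, n))
  stopifnot(length(charge) == n)
  if (is.null(bonds)) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  }
  m <- structure(
    list(
      uuid = uuid, name = name, origin = origin,
      element = as.character(element), charge = charge,
      hcount = rep(0L, n), aromatic = rep(FALSE, n),
      bond_a = as.integer(bonds$a), bond_b = as.integer(bonds$b),
      bond_order = as.integer(bonds$order),
      bond_aromatic = rep(FALSE, nrow(bonds))
    ),
    class = "npl_mol"
  )
  validate_mol(m)
  if (perceive) m <- mol_perceive(m)
  m
}

validate_mol <- function(m) {
  n <- length(m$element)
  if (length(m$bond_a)) {
    if (any(m$bond_a < 1L | m$bond_a > n | m$bond_b < 1L | m$bond_b > n))
      abort("bond endpoint out of range", class = "npl_invalid_molecule")
    if (any(m$bond_a == m$bond_b))
      abort("self-bond not allowed", class = "npl_invalid_molecule")
    key <- paste(pmin(m$bond_a, m$bond_b), pmax(m$bond_a, m$bond_b))
    if (anyDuplicated(key))
      abort("duplicate bond", class = "npl_invalid_molecule")
    if (!all(m$bond_order %in% 1:3))
      abort("bond order must be 1, 2 or 3", class = "npl_invalid_molecule")
  }
  invisible(m)
}

#' @export
print.npl_mol <- function(x, ...) {
  cat(sprintf(
    "<npl_mol> %d heavy atoms, %d bonds  [%s]%s\n",
    mol_n_atoms(x), length(x$bond_a),
    paste(sort(unique(x$element)), collapse = ","),
    if (is.na(x$uuid)) "" else paste0("  uuid=", x$uuid)
  ))
  invisible(x)
}

#' @export
format.npl_mol <- function(x, ...) {
  sprintf("<mol %da %db>", mol_n_atoms(x), length(x$bond_a))
}

#' Heavy-atom count of a molecule
#' @param m an `npl_mol`.
#' @return integer number of heavy atoms.
#' @export
mol_n_atoms <- function(m) length(m$element)

#' Atom table of a molecule
#' @param m an `npl_mol`.
#' @return a tibble with one row per heavy atom.
#' @export
mol_atoms <- function(m) {
  tibble(
    atom = seq_along(m$element), element = m$element, charge = m$charge,
    hcount = m$hcount, aromatic = m$aromatic
  )
}

#' Bond table of a molecule
#' @param m an `npl_mol`.
#' @return a tibble with one row per bond.
#' @export
mol_bonds <- function(m) {
  tibble(
    a = m$bond_a, b = m$bond_b, order = m$bond_order,
    aromatic = m$bond_aromatic
  )
}

# adjacency list: for each atom, integer vector of (neighbour, bond row)
mol_adjacency <- function(m) {
  n <- mol_n_atoms(m)
  adj <- vector("list", n)
  if (length(m$bond_a)) {
    ends <- c(m$bond_a, m$bond_b)
    other <- c(m$bond_b, m$bond_a)
    rows <- rep(seq_along(m$bond_a), 2L)
    sp <- split(seq_along(ends), factor(ends, levels = seq_len(n)))
    for (v in seq_len(n)) {
      i <- sp[[v]]
      adj[[v]] <- cbind(nb = other[i], bond = rows[i])
    }
  } else {
    for (v in seq_len(n)) adj[[v]] <- cbind(nb = integer(), bond = integer())
  }
  adj
}

#' Connected components of a molecule
#' @param m an `npl_mol`.
#' @return integer vector assigning each atom a component id (1, 2, ...).
#' @export
mol_components <- function(m) {
  n <- mol_n_atoms(m)
  comp <- integer(n)
  adj <- mol_adjacency(m)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]][, "nb"]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Induced subgraph of a molecule
#'
#' Keeps the given atoms (in increasing index order) and all bonds among
#' them; uuid, name and origin are retained.
#'
#' @param m an `npl_mol`.
#' @param atoms integer vector of atom indices to keep.
#' @return an `npl_mol`, or NULL when `atoms` is empty.
#' @export
mol_subset <- function(m, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  if (!length(atoms)) return(NULL)
  map <- integer(mol_n_atoms(m))
  map[atoms] <- seq_along(atoms)
  keep <- m$bond_a %in% atoms & m$bond_b %in% atoms
  out <- m
  out$element <- m$element[atoms]
  out$charge <- m$charge[atoms]
  out$hcount <- m$hcount[atoms]
  out$aromatic <- m$aromatic[atoms]
  out$bond_a <- map[m$bond_a[keep]]
  out$bond_b <- map[m$bond_b[keep]]
  out$bond_order <- m$bond_order[keep]
  out$bond_aromatic <- m$bond_aromatic[keep]
  out
}

#' Remove atoms from a molecule
#' @param m an `npl_mol`.
#' @param atoms integer vector of atom indices to delete.
#' @return an `npl_mol`, or NULL when nothing remains.
#' @export
mol_delete_atoms <- function(m, atoms) {
  mol_subset(m, setdiff(seq_len(mol_n_atoms(m)), atoms))
}

#' Disjoint union of two molecules
#'
#' The second molecule's atoms are appended after the first's; the uuid,
#' name and origin of the first are retained.
#'
#' @param m1,m2 `npl_mol` objects.
#' @return an `npl_mol`.
#' @export
mol_combine <- function(m1, m2) {
  off <- mol_n_atoms(m1)
  out <- m1
  out$element <- c(m1$element, m2$element)
  out$charge <- c(m1$charge, m2$charge)
  out$hcount <- c(m1$hcount, m2$hcount)
  out$aromatic <- c(m1$aromatic, m2$aromatic)
  out$bond_a <- c(m1$bond_a, m2$bond_a + off)
  out$bond_b <- c(m1$bond_b, m2$bond_b + off)
  out$bond_order <- c(m1$bond_order, m2$bond_order)
  out$bond_aromatic <- c(m1$bond_aromatic, m2$bond_aromatic)
  out
}

# Add a single bond between two atoms (used by the fixture assembler).
mol_add_bond <- function(m, a, b, order = 1L) {
  m$bond_a <- c(m$bond_a, as.integer(a))
  m$bond_b <- c(m$bond_b, as.integer(b))
  m$bond_order <- c(m$bond_order, as.integer(order))
  m$bond_aromatic <- c(m$bond_aromatic, FALSE)
  validate_mol(m)
  m
}

# Effective valence given element, formal charge and bond-order sum: the
# smallest tabulated valence (charge-adjusted) that accommodates the bonds,
# or the largest one when even that is exceeded. NA for elements without a
# tabulated valence (no implicit hydrogens are added there).
effective_valence <- function(element, charge, bsum = 0) {
  mapply(function(el, ch, bs) {
    v <- .npl_valence[[el]]
    if (is.null(v)) return(NA_real_)
    v <- if (el == "C") v - abs(ch) else v + ch
    v <- pmax(v, 0)
    fit <- v[v >= bs]
    if (length(fit)) min(fit) else max(v)
  }, element, charge, bsum, USE.NAMES = FALSE)
}

#' Derive implicit hydrogens and aromaticity
#'
#' Fills each atom's implicit-hydrogen count from its default valence
#' (adjusted for formal charge) minus its bond-order sum, then perceives
#' aromaticity with a Hueckel-style electron count on 5- and 6-membered
#' rings. The same perception runs at training and at scoring time so that
#' corpus and query signatures always agree.
#'
#' @param m an `npl_mol`.
#' @return the molecule with `hcount`, `aromatic` and bond aromatic flags set.
#' @export
mol_perceive <- function(m) {
  n <- mol_n_atoms(m)
  bsum <- numeric(n)
  if (length(m$bond_a)) {
    tab <- tapply(c(m$bond_order, m$bond_order),
                  factor(c(m$bond_a, m$bond_b), levels = seq_len(n)), sum)
    bsum <- ifelse(is.na(tab), 0, tab)
  }
  ev <- effective_valence(m$element, m$charge, bsum)
  m$hcount <- as.integer(pmax(0, ifelse(is.na(ev), 0, ev - bsum)))
  perceive_aromaticity(m)
}

# Simple cycles of length 3..max_size, one entry per distinct atom set.
# Each cycle is returned in traversal order starting at its smallest atom.
mol_rings <- function(m, max_size = 7L) {
  adj <- mol_adjacency(m)
  n <- mol_n_atoms(m)
  rings <- list()
  seen <- character()
  path <- integer(max_size)
  walk <- function(start, v, depth, onpath) {
    for (u in adj[[v]][, "nb"]) {
      if (u == start && depth >= 3L) {
        cyc <- path[seq_len(depth)]
        key <- paste(sort(cyc), collapse = ".")
        if (!key %in% seen) {
          seen[[length(seen) + 1L]] <<- key
          rings[[length(rings) + 1L]] <<- cyc
        }
      } else if (u > start && !onpath[u] && depth < max_size) {
        path[depth + 1L] <<- u
        onpath[u] <- TRUE
        walk(start, u, depth + 1L, onpath)
        onpath[u] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    if (nrow(adj[[s]]) < 2L) next
    onpath <- logical(n)
    onpath[s] <- TRUE
    path[1L] <- s
    walk(s, s, 1L, onpath)
  }
  rings
}

# Hueckel-style perception on individual 5/6-rings: every ring atom must be
# sp2-capable and the ring's pi-electron count must be 6. Iterated so a ring
# that only aromatizes once a fused neighbour is aromatic is still found.
perceive_aromaticity <- function(m) {
  m$aromatic[] <- FALSE
  m$bond_aromatic[] <- FALSE
  if (!length(m$bond_a)) return(m)
  rings <- Filter(function(r) length(r) %in% c(5L, 6L), mol_rings(m, 6L))
  if (!length(rings)) return(m)
  bond_key <- paste(pmin(m$bond_a, m$bond_b), pmax(m$bond_a, m$bond_b))
  bond_of <- function(a, b) match(paste(pmin(a, b), pmax(a, b)), bond_key)
  repeat {
    changed <- FALSE
    for (r in rings) {
      k <- length(r)
      rb <- bond_of(r, r[c(2:k, 1L)])
      if (all(m$bond_aromatic[rb])) next
      pi <- 0
      ok <- TRUE
      for (i in seq_len(k)) {
        v <- r[i]
        el <- m$element[v]
        in_ring_double <- any(m$bond_order[rb[c(i, if (i == 1L) k else i - 1L)]] == 2L)
        in_ring_arom <- any(m$bond_aromatic[rb[c(i, if (i == 1L) k else i - 1L)]])
        all_b <- which(m$bond_a == v | m$bond_b == v)
        exo_double <- any(m$bond_order[setdiff(all_b, rb)] >= 2L)
        if (!el %in% c("C", "N", "O", "S", "Se")) { ok <- FALSE; break }
        if (in_ring_double || in_ring_arom) {
          pi <- pi + 1
        } else if (el %in% c("N", "O", "S", "Se")) {
          pi <- pi + 2
        } else if (el == "C" && m$charge[v] < 0L) {
          pi <- pi + 2
        } else if (el == "C" && (exo_double || m$charge[v] > 0L)) {
          pi <- pi + 0
        } else {
          ok <- FALSE  # sp3 carbon breaks conjugation
          break
        }
      }
      if (ok && pi == 6) {
        m$aromatic[r] <- TRUE
        m$bond_aromatic[rb] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Validate valences of a molecule
#'
#' Checks that no atom's bond-order sum exceeds its effective valence
#' (default valence adjusted for formal charge); elements without a
#' tabulated valence are skipped.
#'
#' @param m an `npl_mol`.
#' @return TRUE invisibly, or an error describing the offending atom.
#' @export
mol_check_valence <- function(m) {
  n <- mol_n_atoms(m)
  bsum <- numeric(n)
  if (length(m$bond_a)) {
    tab <- tapply(c(m$bond_order, m$bond_order),
                  factor(c(m$bond_a, m$bond_b), levels = seq_len(n)), sum)
    bsum <- ifelse(is.na(tab), 0, tab)
  }
  ev <- effective_valence(m$element, m$charge, bsum)
  bad <- which(!is.na(ev) & bsum > ev)
  if (length(bad)) {
    abort(sprintf("valence exceeded at atom %d (%s: %g bonds, valence %g)",
                  bad[1L], m$element[bad[1L]], bsum[bad[1L]], ev[bad[1L]]),
          class = "npl_invalid_molecule")
  }
  invisible(TRUE)
}
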