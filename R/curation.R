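#' Curation configuration
#'
#' Standardisation settings applied before signature generation: minimum
#' heavy-atom count for a disconnected fragment to be retained (default 6),
#' the element whitelist (non-metals: C, H, N, O, P, S, F, Cl, Br, I, As,
#' Se, B), and whether sugar moieties are removed.
#'
#' @param min_fragment_atoms minimum heavy atoms per retained fragment.
#' @param allowed_elements character vector of allowed element symbols.
#' @param remove_sugars remove glycosidically linked sugars (default TRUE)?
#' @return a `npl_curation_config` list.
#' @export
curation_config <- function(min_fragment_atoms = 6L,
                            allowed_elements = c("C", "H", "N", "O", "P", "S",
                                                 "F", "Cl", "Br", "I", "As",
                                                 "Se", "B"),
                            remove_sugars = TRUE) {
  stopifnot(min_fragment_atoms >= 1L, length(allowed_elements) > 0L)
  structure(
    list(min_fragment_atoms = as.integer(min_fragment_atoms),
         allowed_elements = allowed_elements,
         remove_sugars = isTRUE(remove_sugars)),
    class = "npl_curation_config"
  )
}

#' Drop small disconnected components
#'
#' Deletes connected components with fewer than `min_fragment_atoms` heavy
#' atoms (counter-ions, solvent). Surviving components stay together in one
#' record under the original UUID.
#'
#' @param mol an [npl_mol()].
#' @param min_fragment_atoms heavy-atom cutoff (default 6).
#' @return the filtered molecule, or NULL when nothing survives.
#' @export
filter_small_components <- function(mol, min_fragment_atoms = 6L) {
  comp <- mol_components(mol)
  sizes <- tabulate(comp)
  keep <- which(sizes[comp] >= min_fragment_atoms)
  if (!length(keep)) return(NULL)
  mol_subset(mol, keep)
}

#' Element whitelist filter
#'
#' @param mol an [npl_mol()].
#' @param allowed_elements character vector of allowed element symbols.
#' @return TRUE when every atom's element is whitelisted, FALSE otherwise.
#' @export
filter_elements <- function(mol,
                            allowed_elements = curation_config()$allowed_elements) {
  all(mol$element %in% allowed_elements)
}

#' Find ring sugars
#'
#' A ring sugar is a 5- or 6-membered ring with exactly one ring oxygen and
#' carbon at every other position, no carbon-carbon double bond inside the
#' ring, and at least (ring size - 3) ring carbons bearing an exocyclic
#' single-bonded oxygen. This captures furanose and pyranose rings while
#' excluding plain cyclic ethers such as tetrahydrofuran.
#'
#' @param mol an [npl_mol()].
#' @return a list of integer atom-index sets, fused matches merged.
#' @export
find_ring_sugars <- function(mol) {
  rings <- Filter(function(r) length(r) %in% c(5L, 6L), mol_rings(mol, 6L))
  if (!length(rings)) return(list())
  bond_key <- paste(pmin(mol$bond_a, mol$bond_b), pmax(mol$bond_a, mol$bond_b))
  bond_of <- function(a, b) match(paste(pmin(a, b), pmax(a, b)), bond_key)
  hits <- list()
  for (r in rings) {
    k <- length(r)
    els <- mol$element[r]
    if (sum(els == "O") != 1L || !all(els %in% c("C", "O"))) next
    rb <- bond_of(r, r[c(2:k, 1L)])
    cc <- mol$element[mol$bond_a[rb]] == "C" & mol$element[mol$bond_b[rb]] == "C"
    if (any(mol$bond_order[rb] == 2L & cc)) next
    ring_c <- r[els == "C"]
    n_exo_o <- sum(vapply(ring_c, function(v) {
      rows <- which((mol$bond_a == v | mol$bond_b == v) & mol$bond_order == 1L)
      nb <- ifelse(mol$bond_a[rows] == v, mol$bond_b[rows], mol$bond_a[rows])
      any(mol$element[nb] == "O" & !nb %in% r)
    }, logical(1)))
    if (n_exo_o < k - 3L) next
    hits[[length(hits) + 1L]] <- sort(r)
  }
  .merge_overlapping(hits)
}

.merge_overlapping <- function(sets) {
  if (length(sets) < 2L) return(sets)
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sets
}

#' Find linear sugars
#'
#' A linear sugar is an acyclic chain of three or more contiguous sp3
#' carbons, each bearing exactly one single-bonded oxygen substituent and
#' none of them part of a ring — open-chain polyol/saccharide fragments,
#' while isolated diols stay untouched.
#'
#' @param mol an [npl_mol()].
#' @return a list of integer atom-index sets (the chain carbons).
#' @export
find_linear_sugars <- function(mol) {
  n <- mol_n_atoms(mol)
  if (!n) return(list())
  in_ring <- logical(n)
  for (r in mol_rings(mol, 7L)) in_ring[r] <- TRUE
  cand <- logical(n)
  for (v in seq_len(n)) {
    if (mol$element[v] != "C" || in_ring[v]) next
    rows <- which(mol$bond_a == v | mol$bond_b == v)
    if (any(mol$bond_order[rows] > 1L)) next  # not sp3
    nb <- ifelse(mol$bond_a[rows] == v, mol$bond_b[rows], mol$bond_a[rows])
    n_o <- sum(mol$element[nb] == "O" & !in_ring[nb])
    cand[v] <- n_o == 1L
  }
  if (!any(cand)) return(list())
  # connected groups of candidate carbons joined by C-C single bonds
  sub <- which(cand)
  keep <- mol$bond_a %in% sub & mol$bond_b %in% sub & mol$bond_order == 1L
  comp_of <- seq_len(n)
  find <- function(x) { while (comp_of[x] != x) x <- comp_of[x]; x }
  for (i in which(keep)) {
    ra <- find(mol$bond_a[i]); rb <- find(mol$bond_b[i])
    if (ra != rb) comp_of[ra] <- rb
  }
  groups <- split(sub, vapply(sub, find, integer(1)))
  unname(Filter(function(g) length(g) >= 3L, lapply(groups, sort)))
}

# sugar "unit" = detected atoms, their single-bonded oxygen substituents and
# terminal hydroxymethyl-type arms (an acyclic sp3 carbon whose remaining
# neighbours are all terminal oxygens, e.g. glucose C6). A unit is removable
# when every bond leaving it starts at one of its oxygens, i.e. the sugar
# hangs off the scaffold by glycosidic-type C-O links only.
.sugar_units <- function(mol) {
  cores <- c(find_ring_sugars(mol), find_linear_sugars(mol))
  if (!length(cores)) return(list())
  n <- mol_n_atoms(mol)
  deg <- tabulate(c(mol$bond_a, mol$bond_b), nbins = n)
  in_ring <- logical(n)
  for (r in mol_rings(mol, 7L)) in_ring[r] <- TRUE
  has_multi <- logical(n)
  multi <- mol$bond_order > 1L
  has_multi[unique(c(mol$bond_a[multi], mol$bond_b[multi]))] <- TRUE
  neighbours <- function(v) {
    rows <- which(mol$bond_a == v | mol$bond_b == v)
    ifelse(mol$bond_a[rows] == v, mol$bond_b[rows], mol$bond_a[rows])
  }
  lapply(cores, function(core) {
    unit <- core
    for (v in core) {
      for (u in neighbours(v)) {
        if (u %in% unit) next
        if (mol$element[u] == "O" && !has_multi[u]) {
          unit <- c(unit, u)
        } else if (mol$element[u] == "C" && !in_ring[u] && !has_multi[u]) {
          # terminal hydroxymethyl-type arm (e.g. glucose C6-O6)
          others <- setdiff(neighbours(u), v)
          if (length(others) && all(mol$element[others] == "O" &
                                      deg[others] == 1L))
            unit <- c(unit, u, others)
        }
      }
    }
    sort(unique(unit))
  })
}

.unit_removable <- function(mol, unit) {
  rows <- which(xor(mol$bond_a %in% unit, mol$bond_b %in% unit))
  if (!length(rows)) return(TRUE)
  inside <- ifelse(mol$bond_a[rows] %in% unit, mol$bond_a[rows], mol$bond_b[rows])
  all(mol$element[inside] == "O")
}

#' Remove sugar moieties
#'
#' Iteratively deletes terminal sugar units — a detected ring or linear
#' sugar together with its oxygen substituents, including the glycosidic
#' oxygen — whenever all of the unit's links to the rest of the molecule run
#' through those oxygens. The bridging oxygen is deleted with the sugar, so
#' a clean aglycone remains; carbon-linked (C-glycosidic) sugars are kept.
#' Components that fall below `min_fragment_atoms` after removal are
#' deleted. A molecule that is entirely sugar comes back as NULL.
#'
#' @param mol an [npl_mol()].
#' @param min_fragment_atoms heavy-atom cutoff applied after removal.
#' @return the deglycosylated molecule (same UUID), or NULL.
#' @export
remove_sugars <- function(mol, min_fragment_atoms = 6L) {
  changed <- TRUE
  while (changed && !is.null(mol)) {
    changed <- FALSE
    units <- Filter(function(u) .unit_removable(mol, u), .sugar_units(mol))
    if (length(units)) {
      mol <- mol_delete_atoms(mol, unique(unlist(units)))
      changed <- TRUE
    }
  }
  if (is.null(mol)) return(NULL)
  filter_small_components(mol, min_fragment_atoms)
}

#' Curate a batch of molecules
#'
#' Applies, in order: small-component removal, the element whitelist, sugar
#' removal, and a final fragment-size filter; kept records are split into
#' connected fragments that share the parent's UUID, so downstream signing
#' and scoring treat them as one molecule. Every input UUID is accounted for
#' in either the kept or the discarded table.
#'
#' @param mols a tibble with columns `uuid`, `mol` (and optionally `name`),
#'   as returned by [read_molecules()] or the fixture generators.
#' @param config a [curation_config()].
#' @return an object of class `npl_curation` with elements `kept` (tibble:
#'   `uuid`, `name`, `mol`, `fragment`), `discarded` (tibble: `uuid`,
#'   `reason`) and `stats` (tibble: `reason`, `n`).
#' @export
curate <- function(mols, config = curation_config()) {
  stopifnot(inherits(config, "npl_curation_config"))
  kept <- list()
  discarded <- list()
  reasons <- c("metal_element", "empty_after_curation", "too_small")
  recs <- .as_mol_list(mols)
  for (m in recs) {
    m2 <- filter_small_components(m, config$min_fragment_atoms)
    if (is.null(m2)) {
      discarded[[length(discarded) + 1L]] <- list(uuid = m$uuid, reason = "too_small")
      next
    }
    if (!filter_elements(m2, config$allowed_elements)) {
      discarded[[length(discarded) + 1L]] <- list(uuid = m$uuid, reason = "metal_element")
      next
    }
    if (config$remove_sugars) {
      m2 <- remove_sugars(m2, config$min_fragment_atoms)
      if (is.null(m2)) {
        discarded[[length(discarded) + 1L]] <-
          list(uuid = m$uuid, reason = "empty_after_curation")
        next
      }
      m2 <- mol_perceive(m2)
    }
    comp <- mol_components(m2)
    for (ci in seq_len(max(comp))) {
      frag <- mol_subset(m2, which(comp == ci))
      kept[[length(kept) + 1L]] <- list(
        uuid = m$uuid, name = m$name %||% NA_character_, mol = frag,
        fragment = ci
      )
    }
  }
  kept_tbl <- if (length(kept)) {
    tibble(
      uuid = vapply(kept, `[[`, character(1), "uuid"),
      name = vapply(kept, `[[`, character(1), "name"),
      mol = purrr::map(kept, "mol"),
      fragment = vapply(kept, `[[`, integer(1), "fragment")
    )
  } else {
    tibble(uuid = character(), name = character(), mol = list(),
           fragment = integer())
  }
  disc_tbl <- if (length(discarded)) {
    tibble(
      uuid = vapply(discarded, `[[`, character(1), "uuid"),
      reason = vapply(discarded, `[[`, character(1), "reason")
    )
  } else {
    tibble(uuid = character(), reason = character())
  }
  stats <- tibble(reason = reasons,
                  n = vapply(reasons, function(r) sum(disc_tbl$reason == r),
                             integer(1), USE.NAMES = FALSE))
  structure(list(kept = kept_tbl, discarded = disc_tbl, stats = stats,
                 config = config),
            class = "npl_curation")
}

#' @export
print.npl_curation <- function(x, ...) {
  cat(sprintf("<npl_curation> kept %d fragment(s) of %d molecule(s); discarded %d\n",
              nrow(x$kept), dplyr::n_distinct(x$kept$uuid), nrow(x$discarded)))
  for (i in seq_len(nrow(x$stats))) {
    if (x$stats$n[i] > 0)
      cat(sprintf("  %-22s %d\n", x$stats$reason[i], x$stats$n[i]))
  }
  invisible(x)
}

#' Tidy a curation outcome
#'
#' @param x an `npl_curation` object.
#' @param ... unused.
#' @return a tibble with one row per input molecule: `uuid`, `status`
#'   (kept/discarded), `reason` (NA when kept) and `n_fragments`.
#' @importFrom generics tidy
#' @export
tidy.npl_curation <- function(x, ...) {
  kept <- x$kept |>
    dplyr::count(.data$uuid, name = "n_fragments") |>
    dplyr::mutate(status = "kept", reason = NA_character_)
  disc <- x$discarded |>
    dplyr::mutate(status = "discarded", n_fragments = 0L)
  dplyr::bind_rows(kept, disc)[, c("uuid", "status", "reason", "n_fragments")]
}

#' Summarise a curation outcome
#'
#' @param x an `npl_curation` object.
#' @param ... unused.
#' @return a one-row tibble of counts.
#' @importFrom generics glance
#' @export
glance.npl_curation <- function(x, ...) {
  tibble(
    n_input = dplyr::n_distinct(c(x$kept$uuid, x$discarded$uuid)),
    n_kept = dplyr::n_distinct(x$kept$uuid),
    n_fragments = nrow(x$kept),
    n_discarded = nrow(x$discarded),
    n_metal_element = x$stats$n[x$stats$reason == "metal_element"],
    n_empty_after_curation = x$stats$n[x$stats$reason == "empty_after_curation"],
    n_too_small = x$stats$n[x$stats$reason == "too_small"]
  )
}
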