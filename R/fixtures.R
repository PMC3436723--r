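#' Fixture corpus configuration
#'
#' Settings for the seeded molecule generators. The two grammars emulate
#' the structural contrast between a natural-product collection (fused
#' saturated carbocycles, high oxygen content, optional glycoside
#' appendages) and a lead-like synthetic collection (flat heteroaromatics,
#' halogens, amide/sulfonamide linkers, occasional counter-ions and
#' metal-organic records for exercising curation). The same config always
#' produces byte-identical corpora.
#'
#' @param seed integer RNG seed.
#' @param n_np number of natural-product-like molecules.
#' @param n_sm number of synthetic-like molecules.
#' @param sugar_fraction probability that an NP-like molecule carries a
#'   pyranose attached through a glycosidic C-O bond.
#' @param counterion_fraction probability that a synthetic-like record
#'   carries a small disconnected counter-ion.
#' @param metal_fraction probability that a synthetic-like record contains
#'   a non-whitelisted element (Fe).
#' @return a `npl_fixture_config` list.
#' @export
fixture_config <- function(seed = 42L, n_np = 200L, n_sm = 200L,
                           sugar_fraction = 0.3, counterion_fraction = 0.15,
                           metal_fraction = 0.05) {
  stopifnot(
    sugar_fraction >= 0, sugar_fraction <= 1,
    counterion_fraction >= 0, counterion_fraction <= 1,
    metal_fraction >= 0, metal_fraction <= 1
  )
  structure(
    list(seed = as.integer(seed), n_np = as.integer(n_np),
         n_sm = as.integer(n_sm), sugar_fraction = sugar_fraction,
         counterion_fraction = counterion_fraction,
         metal_fraction = metal_fraction),
    class = "npl_fixture_config"
  )
}

# run code under a private, seeded RNG without touching the caller's stream
.with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# ---- building blocks ------------------------------------------------------

.bond_df <- function(...) {
  b <- matrix(c(...), ncol = 3L, byrow = TRUE)
  data.frame(a = b[, 1L], b = b[, 2L], order = b[, 3L])
}

# a block is a perceived molecule plus its free-valence vector
.blk <- function(element, bonds = NULL, charge = NULL, attach = NA_integer_,
                 free = NULL) {
  m <- npl_mol(element, charge, bonds)
  list(mol = m, free = free %||% m$hcount, attach = attach)
}

.np_scaffolds <- function() list(
  cyclohexane = .blk(rep("C", 6), .bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,1,1)),
  cyclopentane = .blk(rep("C", 5), .bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,1,1)),
  decalin = .blk(rep("C", 10), .bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,1,1,
                                        5,7,1, 7,8,1, 8,9,1, 9,10,1, 10,6,1)),
  bicyclooctane = .blk(rep("C", 8), .bond_df(1,2,1, 2,3,1, 3,4,1, 1,5,1, 5,6,1,
                                             6,4,1, 1,7,1, 7,8,1, 8,4,1)),
  lactone = .blk(c("O", rep("C", 5), "O"),
                 .bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,1,1, 2,7,2)),
  oxane = .blk(c("O", rep("C", 5)),
               .bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,1,1)),
  isoprenoid = .blk(rep("C", 5), .bond_df(1,2,1, 2,3,1, 2,4,1, 4,5,1))
)

.np_substituents <- function() list(
  hydroxyl = .blk("O", attach = 1L),
  methyl = .blk("C", attach = 1L),
  methoxy = .blk(c("O", "C"), .bond_df(1,2,1), attach = 1L),
  carboxyl = .blk(c("C", "O", "O"), .bond_df(1,2,2, 1,3,1), attach = 1L),
  amino = .blk("N", attach = 1L)
)

.sm_scaffolds <- function() list(
  benzene = .blk(rep("C", 6), .bond_df(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1)),
  pyridine = .blk(c("N", rep("C", 5)),
                  .bond_df(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1)),
  pyrimidine = .blk(c("N", "C", "N", "C", "C", "C"),
                    .bond_df(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1)),
  thiophene = .blk(c("S", rep("C", 4)), .bond_df(1,2,1, 2,3,2, 3,4,1, 4,5,2, 5,1,1)),
  naphthalene = .blk(rep("C", 10),
                     .bond_df(1,2,2, 2,3,1, 3,4,2, 4,10,1, 10,9,2, 9,1,1,
                              5,6,2, 6,7,1, 7,8,2, 8,10,1, 9,5,1))
)

.sm_linkers <- function() list(
  amide = .blk(c("C", "O", "N"), .bond_df(1,2,2, 1,3,1), attach = c(1L, 3L)),
  sulfonamide = .blk(c("S", "O", "O", "N"), .bond_df(1,2,2, 1,3,2, 1,4,1),
                     attach = c(1L, 4L)),
  ether = .blk("O", attach = c(1L, 1L)),
  ketone = .blk(c("C", "O"), .bond_df(1,2,2), attach = c(1L, 1L)),
  direct = NULL
)

.sm_substituents <- function() list(
  fluoro = .blk("F", attach = 1L),
  chloro = .blk("Cl", attach = 1L),
  bromo = .blk("Br", attach = 1L),
  trifluoromethyl = .blk(c("C", "F", "F", "F"), .bond_df(1,2,1, 1,3,1, 1,4,1),
                         attach = 1L),
  nitro = .blk(c("N", "O", "O"), .bond_df(1,2,2, 1,3,1),
               charge = c(1L, 0L, -1L), attach = 1L),
  cyano = .blk(c("C", "N"), .bond_df(1,2,3), attach = 1L),
  methoxy = .blk(c("O", "C"), .bond_df(1,2,1), attach = 1L),
  methyl = .blk("C", attach = 1L)
)

# beta-D-glucopyranose-style ring; atom 7 is the anomeric oxygen used for
# glycosidic attachment. `drop_o4` omits the C4 hydroxyl so chains can be
# linked sugar-to-sugar through a shared bridging oxygen.
.pyranose <- function(drop_o4 = FALSE) {
  el <- c(rep("C", 5), "O", "O", "O", "O", if (!drop_o4) "O", "C", "O")
  n <- length(el)
  bonds <- rbind(
    c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1), c(5, 6, 1), c(6, 1, 1),
    c(1, 7, 1), c(2, 8, 1), c(3, 9, 1),
    if (!drop_o4) c(4, 10, 1),
    c(5, n - 1L, 1), c(n - 1L, n, 1)
  )
  .blk(el, data.frame(a = bonds[, 1], b = bonds[, 2], order = bonds[, 3]),
       attach = 7L)
}

# ---- assembly -------------------------------------------------------------

.attach_block <- function(state, block, at = NULL, block_at = NULL,
                          order = 1L, target_element = "C") {
  if (is.null(at)) {
    cand <- which(state$free >= order &
                    state$mol$element %in% target_element)
    if (!length(cand)) return(state)  # saturated; skip silently
    at <- cand[[sample.int(length(cand), 1L)]]
  }
  if (is.null(block_at)) {
    block_at <- block$attach[[1L]]
    if (is.na(block_at)) {  # free choice: any block carbon with an open slot
      bc <- which(block$free >= order & block$mol$element == "C")
      block_at <- bc[[sample.int(length(bc), 1L)]]
    }
  }
  off <- mol_n_atoms(state$mol)
  b_at <- block_at + off
  m <- mol_add_bond(mol_combine(state$mol, block$mol), at, b_at, order)
  free <- c(state$free, block$free)
  free[at] <- free[at] - order
  free[b_at] <- free[b_at] - order
  list(mol = m, free = free)
}

.as_state <- function(block) list(mol = block$mol, free = block$free)

.finish_molecule <- function(state, uuid, name) {
  m <- mol_perceive(state$mol)
  m$uuid <- uuid
  m$name <- name
  m$origin <- "generated"
  mol_check_valence(m)
  m
}

.one_np_molecule <- function(scaffolds, subs, sugar_fraction) {
  st <- .as_state(scaffolds[[sample.int(length(scaffolds), 1L)]])
  if (stats::runif(1) < 0.45)
    st <- .attach_block(st, scaffolds[[sample.int(length(scaffolds), 1L)]])
  for (i in seq_len(sample(2:5, 1L))) {
    w <- c(hydroxyl = 0.45, methyl = 0.2, methoxy = 0.1, carboxyl = 0.1,
           amino = 0.15)
    st <- .attach_block(st, subs[[sample(names(w), 1L, prob = w)]])
  }
  if (stats::runif(1) < sugar_fraction) {
    sugar <- .pyranose()
    cand <- which(st$free >= 1L & st$mol$element == "C")
    if (length(cand)) {
      at <- cand[[sample.int(length(cand), 1L)]]
      st <- .attach_block(st, sugar, at = at)
    }
  }
  st
}

.one_sm_molecule <- function(scaffolds, linkers, subs,
                             counterion_fraction, metal_fraction) {
  st <- .as_state(scaffolds[[sample.int(length(scaffolds), 1L)]])
  if (stats::runif(1) < 0.7) {
    ring2 <- scaffolds[[sample.int(length(scaffolds), 1L)]]
    link <- linkers[[sample.int(length(linkers), 1L)]]
    if (is.null(link)) {  # direct ring-ring bond
      st <- .attach_block(st, ring2)
    } else {
      n_before <- mol_n_atoms(st$mol)
      st2 <- .attach_block(st, link, block_at = link$attach[[1L]])
      if (mol_n_atoms(st2$mol) > n_before) {
        exit <- n_before + link$attach[[2L]]
        st <- .attach_block(st2, ring2, at = exit)
      } else {
        st <- .attach_block(st, ring2)
      }
    }
  }
  for (i in seq_len(sample(1:4, 1L))) {
    st <- .attach_block(st, subs[[sample.int(length(subs), 1L)]])
  }
  if (stats::runif(1) < metal_fraction) {
    st <- .attach_block(st, .blk("Fe", free = 2L, attach = 1L))
  }
  if (stats::runif(1) < counterion_fraction) {
    st$mol <- mol_combine(st$mol, npl_mol("Cl", charge = -1L))
    st$free <- c(st$free, 0L)
  }
  st
}

.fixture_tibble <- function(states, prefix, seed) {
  n <- length(states)
  uuids <- npl_uuid(n)
  tibble(
    uuid = uuids,
    name = sprintf("%s-%04d", prefix, seq_len(n)),
    mol = purrr::map2(states, seq_len(n), function(st, i) {
      .finish_molecule(st, uuids[[i]], sprintf("%s-%04d", prefix, i))
    }),
    origin = sprintf("generated(seed=%d)", seed)
  )
}

#' Generate a natural-product-like molecule corpus
#'
#' Seeded, download-free stand-in for an NP training collection: molecules
#' assembled from saturated mono-, fused- and bridged-ring blocks and
#' short branched chains, decorated with oxygen-rich substituents;
#' `sugar_fraction` of them carry a pyranose bound through a glycosidic
#' C-O bond. All outputs are valence-checked.
#'
#' @param config a [fixture_config()].
#' @return a tibble with columns `uuid`, `name`, `mol`, `origin`.
#' @export
generate_np_like <- function(config = fixture_config()) {
  stopifnot(inherits(config, "npl_fixture_config"))
  .with_seed(config$seed, {
    scaffolds <- .np_scaffolds()
    subs <- .np_substituents()
    states <- purrr::map(seq_len(config$n_np), function(i) {
      .one_np_molecule(scaffolds, subs, config$sugar_fraction)
    })
    .fixture_tibble(states, "np-like", config$seed)
  })
}

#' Generate a synthetic-like molecule corpus
#'
#' Seeded stand-in for a lead-like synthetic screening collection: flat
#' (hetero)aromatic rings joined by amide, sulfonamide, ether or ketone
#' linkers and decorated with halogens, nitro, cyano and methoxy groups —
#' a low sp3 fraction and no sugar motifs. A configurable fraction of
#' records carries a disconnected chloride counter-ion or an iron atom so
#' curation filters can be exercised.
#'
#' @param config a [fixture_config()].
#' @return a tibble with columns `uuid`, `name`, `mol`, `origin`.
#' @export
generate_synthetic_like <- function(config = fixture_config()) {
  stopifnot(inherits(config, "npl_fixture_config"))
  .with_seed(config$seed + 1L, {
    scaffolds <- .sm_scaffolds()
    linkers <- .sm_linkers()
    subs <- .sm_substituents()
    states <- purrr::map(seq_len(config$n_sm), function(i) {
      .one_sm_molecule(scaffolds, linkers, subs,
                       config$counterion_fraction, config$metal_fraction)
    })
    .fixture_tibble(states, "synthetic-like", config$seed)
  })
}

#' Fixed panel of degenerate and edge-case molecules
#'
#' A deterministic six-record panel covering the curation corner cases: a
#' single bromide anion, free glucose, two toluene scaffolds bridged by one
#' sugar ring, an all-sugar trisaccharide, a molecule containing every
#' whitelisted element, and benzene with a chloride counter-ion.
#'
#' @return a tibble with columns `uuid`, `name`, `mol`, `origin`.
#' @export
edge_cases <- function() {
  toluene <- function() .blk(rep("C", 7),
                             .bond_df(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1,
                                      1,7,1))
  # sugar bridging two scaffolds: anomeric O7 to one toluene, O10 to another
  bridge <- local({
    st <- .as_state(.pyranose())
    st <- .attach_block(st, toluene(), at = 7L)
    st <- .attach_block(st, toluene(), at = 10L)
    st$mol
  })
  trisaccharide <- local({
    st <- .as_state(.pyranose())
    s2 <- .pyranose(drop_o4 = TRUE)
    s3 <- .pyranose(drop_o4 = TRUE)
    # link anomeric O of sugar n to C4 of sugar n+1
    st <- .attach_block(st, s2, at = 7L, block_at = 4L)
    st <- .attach_block(st, s3, at = mol_n_atoms(st$mol) - 4L, block_at = 4L)
    st$mol
  })
  all_elements <- npl_mol(
    c(rep("C", 7), "F", "Cl", "Br", "I", "N", "O", "S", "P", "As", "Se", "B"),
    bonds = .bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,7,1,
                     1,8,1, 2,9,1, 3,10,1, 4,11,1, 5,12,1, 6,13,1, 7,14,1,
                     12,15,1, 15,16,1, 1,17,1, 17,18,1)
  )
  benzene_chloride <- mol_combine(
    .sm_scaffolds()$benzene$mol,
    npl_mol("Cl", charge = -1L)
  )
  recs <- list(
    `edge-single-atom` = npl_mol("Br", charge = -1L),
    `edge-glucose` = .pyranose()$mol,
    `edge-sugar-bridge` = mol_perceive(bridge),
    `edge-trisaccharide` = mol_perceive(trisaccharide),
    `edge-all-elements` = all_elements,
    `edge-benzene-chloride` = mol_perceive(benzene_chloride)
  )
  tibble(
    uuid = names(recs),
    name = names(recs),
    mol = purrr::map2(recs, names(recs), function(m, u) {
      m$uuid <- u
      m$name <- u
      m$origin <- "edge-case-panel"
      m
    }),
    origin = "edge-case-panel"
  )
}
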