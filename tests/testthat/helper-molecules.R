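# shared builders and independent oracles used across the suite

bond_df <- function(...) {
  b <- matrix(c(...), ncol = 3L, byrow = TRUE)
  data.frame(a = b[, 1L], b = b[, 2L], order = b[, 3L])
}

mol_benzene <- function(uuid = "benzene") {
  m <- npl_mol(rep("C", 6), bonds = bond_df(1,2,2, 2,3,1, 3,4,2, 4,5,1,
                                            5,6,2, 6,1,1))
  m$uuid <- uuid
  m
}

mol_ethanol <- function(uuid = "ethanol") {
  m <- npl_mol(c("C", "C", "O"), bonds = bond_df(1,2,1, 2,3,1))
  m$uuid <- uuid
  m
}

mol_cyclohexane <- function() {
  npl_mol(rep("C", 6), bonds = bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,1,1))
}

mol_glucose <- function(uuid = "glucose") {
  m <- edge_cases()$mol[[2]]
  m$uuid <- uuid
  m
}

# phenyl beta-D-glucoside: glucose anomeric oxygen bonded to a benzene carbon
mol_phenyl_glucoside <- function() {
  g <- mol_glucose()
  b <- mol_benzene()
  m <- mol_combine(g, b)
  m$bond_a <- c(m$bond_a, 7L)       # anomeric O
  m$bond_b <- c(m$bond_b, 13L)      # benzene C1
  m$bond_order <- c(m$bond_order, 1L)
  m$bond_aromatic <- c(m$bond_aromatic, FALSE)
  m$uuid <- "phenyl-glucoside"
  mol_perceive(m)
}

# reorder a molecule's atoms by permutation p (atom i of the result is atom
# p[i] of the input), preserving all perceived attributes
permute_mol <- function(m, p) {
  inv <- order(p)
  out <- m
  out$element <- m$element[p]
  out$charge <- m$charge[p]
  out$hcount <- m$hcount[p]
  out$aromatic <- m$aromatic[p]
  out$bond_a <- inv[m$bond_a]
  out$bond_b <- inv[m$bond_b]
  out
}

# induced subgraph on atoms within graph distance <= h of root (BFS in R,
# independent of the signature engine); returns list(mol, root)
neighborhood_subgraph <- function(m, root, h) {
  n <- mol_n_atoms(m)
  dist <- rep(NA_integer_, n)
  dist[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      if (dist[v] == h) next
      rows <- which(m$bond_a == v | m$bond_b == v)
      nb <- ifelse(m$bond_a[rows] == v, m$bond_b[rows], m$bond_a[rows])
      new <- nb[is.na(dist[nb])]
      dist[new] <- dist[v] + 1L
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  keep <- which(!is.na(dist))
  list(mol = mol_subset(m, keep), root = match(root, keep))
}

atom_key <- function(m) {
  paste(m$element, m$charge, m$hcount, m$aromatic)
}

bond_label <- function(m, row) {
  if (m$bond_aromatic[row]) ":" else as.character(m$bond_order[row])
}

# exhaustive rooted-isomorphism check by label-consistent backtracking;
# the independent oracle for signature equality on small neighbourhoods
rooted_isomorphic <- function(g1, r1, g2, r2) {
  n <- mol_n_atoms(g1)
  if (n != mol_n_atoms(g2)) return(FALSE)
  k1 <- atom_key(g1); k2 <- atom_key(g2)
  if (!identical(sort(k1), sort(k2))) return(FALSE)
  if (length(g1$bond_a) != length(g2$bond_a)) return(FALSE)
  adj <- function(g, v) {
    rows <- which(g$bond_a == v | g$bond_b == v)
    nb <- ifelse(g$bond_a[rows] == v, g$bond_b[rows], g$bond_a[rows])
    stats::setNames(vapply(rows, function(r) bond_label(g, r), character(1)), nb)
  }
  edge1 <- lapply(seq_len(n), function(v) adj(g1, v))
  edge2 <- lapply(seq_len(n), function(v) adj(g2, v))
  map <- rep(NA_integer_, n)
  used <- rep(FALSE, n)
  assign_next <- function(i) {
    if (i > n) return(TRUE)
    v <- ord[i]
    for (w in seq_len(n)) {
      if (used[w] || k1[v] != k2[w]) next
      ok <- TRUE
      e1 <- edge1[[v]]
      # every already-mapped neighbour of v must be a matching neighbour of w
      for (j in seq_along(e1)) {
        u <- as.integer(names(e1)[j])
        if (!is.na(map[u])) {
          e2 <- edge2[[w]]
          hit <- which(as.integer(names(e2)) == map[u])
          if (!length(hit) || e2[[hit[1]]] != e1[[j]]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      # and w must not have mapped neighbours that v lacks
      e2 <- edge2[[w]]
      for (j in seq_along(e2)) {
        u2 <- as.integer(names(e2)[j])
        pre <- which(map == u2)
        if (length(pre) && !pre[1] %in% as.integer(names(e1))) { ok <- FALSE; break }
      }
      if (!ok) next
      map[v] <<- w
      used[w] <<- TRUE
      if (assign_next(i + 1L)) return(TRUE)
      map[v] <<- NA_integer_
      used[w] <<- FALSE
    }
    FALSE
  }
  # BFS order from the root keeps the search anchored
  ord <- integer(0)
  seen <- rep(FALSE, n)
  queue <- r1
  seen[r1] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    ord <- c(ord, v)
    nb <- as.integer(names(edge1[[v]]))
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  ord <- c(ord, which(!seen))
  map[r1] <- r2
  used[r2] <- TRUE
  if (k1[r1] != k2[r2]) return(FALSE)
  assign_next(2L)
}

# element/bond multiset comparison used for file round-trip checks
graph_profile <- function(m) {
  bonds <- sort(paste(
    pmin(m$element[m$bond_a], m$element[m$bond_b]),
    pmax(m$element[m$bond_a], m$element[m$bond_b]),
    m$bond_order
  ))
  list(
    n = mol_n_atoms(m),
    atoms = sort(atom_key(m)),
    bonds = bonds
  )
}

small_fixture_set <- function(n = 50, seed = 7) {
  cfg <- fixture_config(seed = seed, n_np = ceiling(n / 2), n_sm = floor(n / 2),
                        counterion_fraction = 0, metal_fraction = 0)
  rbind(generate_np_like(cfg), generate_synthetic_like(cfg))[seq_len(n), ]
}
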