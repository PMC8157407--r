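# Independent oracles and shared fixtures.  Oracles deliberately use
# different algorithms from the package code paths they check.

# Mann-Whitney pair-counting AUC: every (positive, negative) pair
# contributes 1 if the positive scores higher, 0.5 on ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# brute-force top-n: sort per molecule by (contribution desc, index asc),
# count true atoms in the first n_i slots, pool the ratios
oracle_top_n <- function(contrib_list, true_list) {
  m_sum <- 0
  n_sum <- 0
  for (i in seq_along(contrib_list)) {
    x <- contrib_list[[i]]
    true_idx <- true_list[[i]]
    n_i <- length(true_idx)
    if (n_i == 0) next
    ord <- order(-x, seq_along(x))
    m_sum <- m_sum + sum(ord[seq_len(n_i)] %in% true_idx)
    n_sum <- n_sum + n_i
  }
  if (n_sum == 0) NA_real_ else m_sum / n_sum
}

# brute-force fragment enumerator: delete every subset of 1..max_bonds
# eligible bonds, take connected components by BFS, filter by size
oracle_fragments <- function(record, max_bonds = 3, max_atoms = 7,
                             max_frac = 0.4) {
  a <- record$n_heavy
  bonds <- record$bonds
  elig <- which(bonds$order == 1 & !bonds$ring)
  if (length(elig) == 0) return(list())
  cap <- min(max_atoms, floor(max_frac * a + 1e-9))
  components <- function(deleted) {
    keep <- setdiff(seq_len(nrow(bonds)), deleted)
    adj <- vector("list", a)
    for (k in keep) {
      adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], bonds$b[k])
      adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], bonds$a[k])
    }
    seen <- logical(a)
    comps <- list()
    for (s in seq_len(a)) {
      if (seen[s]) next
      queue <- s
      seen[s] <- TRUE
      comp <- c()
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        comp <- c(comp, v)
        for (u in adj[[v]]) {
          if (!seen[u]) {
            seen[u] <- TRUE
            queue <- c(queue, u)
          }
        }
      }
      comps[[length(comps) + 1L]] <- sort(comp)
    }
    comps
  }
  found <- new.env()
  for (nb in seq_len(min(max_bonds, length(elig)))) {
    for (subset in utils::combn(length(elig), nb, simplify = FALSE)) {
      del <- elig[subset]
      for (comp in components(del)) {
        if (length(comp) > cap || length(comp) == a) next
        # component boundary must be exactly bonds that were deleted --
        # i.e. all crossing bonds deleted (always true for components) --
        # and the component must actually be separated (>=1 crossing)
        inside <- logical(a)
        inside[comp] <- TRUE
        cross <- xor(inside[bonds$a], inside[bonds$b])
        if (sum(cross) < 1) next
        assign(paste(comp, collapse = ","), sum(cross), envir = found)
      }
    }
  }
  keys <- ls(found)
  lapply(keys, function(k)
    list(atoms = as.integer(strsplit(k, ",")[[1]]),
         n_broken_bonds = get(k, envir = found)))
}

# oracle predictors honouring the masked-prediction contract
oracle_count_n <- function(record, mask) {
  live <- setdiff(seq_len(record$n_heavy), mask)
  sum(record$atoms$symbol[live] == "N")
}
oracle_n_minus_o <- function(record, mask) {
  live <- setdiff(seq_len(record$n_heavy), mask)
  sum(record$atoms$symbol[live] == "N") -
    sum(record$atoms$symbol[live] == "O")
}
oracle_additive <- function(weights) {
  function(record, mask) {
    live <- setdiff(seq_len(record$n_heavy), mask)
    sum(weights[live])
  }
}

# quick builders
make_contrib <- function(x, id = "m", level = "atom",
                         targets = as.list(seq_along(x)), base = 0) {
  new_contrib_vector(id, level, targets, x, base)
}
make_truth <- function(expected, id = "m") new_atom_truth(id, expected)

# shared fixture pool, generated once per test run (backend calls are
# slow); access via shared_pool()
.pool_cache <- new.env()
shared_pool <- function(n = 50, seed = 101, profile = "general") {
  key <- paste(n, seed, profile, sep = "_")
  if (is.null(.pool_cache[[key]])) {
    .pool_cache[[key]] <- generate_fixture_pool(n, seed, profile)
  }
  .pool_cache[[key]]
}

# hand-placed conformer injection for pharmacophore tests
inject_conformer <- function(record, coords) {
  stopifnot(nrow(coords) == record$n_heavy)
  colnames(coords) <- c("x", "y", "z")
  record$conformers <- c(record$conformers, list(coords))
  record
}
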