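# Independent brute-force oracles used to validate the interval and duplex
# engines. These deliberately materialize base-position sets / enumerate all
# co-fold structures rather than reusing any package code path.

# base positions covered by a 0-based half-open interval, tagged by chrom+strand
brute_positions <- function(chrom, start, end, strand = "+") {
  paste(chrom, strand, seq(start, end - 1))
}

brute_jaccard <- function(a, b) {
  pa <- brute_positions(a$chrom, a$start, a$end, a$strand %||% "+")
  pb <- brute_positions(b$chrom, b$start, b$end, b$strand %||% "+")
  length(intersect(pa, pb)) / length(union(pa, pb))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force consensus: sets + BFS connected components. Returns the set of
# retained components as canonical keys (sorted "replicate:peak_id" strings).
brute_consensus <- function(peaks, threshold, min_replicates = 2,
                            aggregation = "any_pair") {
  n <- nrow(peaks)
  pos <- lapply(seq_len(n), function(i)
    brute_positions(peaks$chrom[i], peaks$start[i], peaks$end[i],
                    peaks$strand[i]))
  adj <- lapply(seq_len(n), function(i) integer())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (peaks$replicate_id[i] != peaks$replicate_id[j] &&
        length(intersect(pos[[i]], pos[[j]])) >= 1) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- rep(NA_integer_, n); cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1; queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  keys <- character()
  for (k in unique(comp)) {
    idx <- which(comp == k)
    reps <- peaks$replicate_id[idx]
    if (length(unique(reps)) < min_replicates) next
    pairs <- t(combn(idx, 2))
    cross <- peaks$replicate_id[pairs[, 1]] != peaks$replicate_id[pairs[, 2]]
    pairs <- pairs[cross, , drop = FALSE]
    jac <- vapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      length(intersect(pos[[i]], pos[[j]])) /
        length(union(pos[[i]], pos[[j]]))
    }, 0)
    ok <- if (aggregation == "any_pair") any(jac >= threshold)
      else if (aggregation == "all_pairs") all(jac >= threshold)
      else {
        foot <- lapply(split(idx, reps), function(ii)
          unique(unlist(pos[ii])))
        length(Reduce(intersect, foot)) /
          length(unique(unlist(pos[idx]))) >= threshold
      }
    if (ok)
      keys <- c(keys, paste(sort(paste(reps, peaks$peak_id[idx], sep = ":")),
                            collapse = "|"))
  }
  sort(keys)
}

consensus_keys <- function(cons) {
  if (nrow(cons) == 0) return(character())
  sort(vapply(cons$members, function(m)
    paste(sort(paste(m$replicate_id, m$peak_id, sep = ":")), collapse = "|"),
    ""))
}

# random multi-replicate peak fixture for the consensus oracle
random_replicate_peaks <- function() {
  n_rep <- sample(2:4, 1)
  bind_rows(lapply(seq_len(n_rep), function(r) {
    n_pk <- sample(2:5, 1)
    start <- sample(0:300, n_pk)
    tibble::tibble(
      replicate_id = paste0("rep", r),
      chrom = sample(c("chr1", "chr2"), n_pk, replace = TRUE),
      start = start, end = start + sample(10:60, n_pk, replace = TRUE),
      strand = sample(c("+", "-"), n_pk, replace = TRUE),
      peak_id = paste0("r", r, "p", seq_len(n_pk)))
  }))
}

# ---- exhaustive co-fold enumeration oracle ------------------------------

pair_e <- function(a, b, model) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(model$gc)
  if (key %in% c("AU", "UA")) return(model$au)
  if (key %in% c("GU", "UG")) return(model$gu)
  NA_real_
}

# energy of a complete structure: a matrix of (mir_pos, win_pos) pairs
energy_of_structure <- function(pairs, mirv, winv, model) {
  ord <- order(pairs[, 1])
  mp <- pairs[ord, 1]; wp <- pairs[ord, 2]
  e <- model$init_penalty
  for (t in seq_along(mp)) e <- e + pair_e(mirv[mp[t]], winv[wp[t]], model)
  if (length(mp) > 1) for (t in seq_len(length(mp) - 1)) {
    a <- mp[t + 1] - mp[t] - 1
    b <- wp[t] - wp[t + 1] - 1
    e <- e + if (a > 0 && b > 0) model$loop_per_nt * (a + b)
             else model$bulge_per_nt * (a + b)
  }
  e
}

# all monotone extensions (i increasing, j decreasing) from a boundary pair
enum_chains <- function(mirv, winv, i0, j0, dir, model) {
  out <- list(matrix(numeric(0), ncol = 2))
  i_range <- if (dir > 0) seq_len(length(mirv)) else rev(seq_len(length(mirv)))
  for (i2 in i_range) {
    if (dir > 0 && i2 <= i0) next
    if (dir < 0 && i2 >= i0) next
    for (j2 in seq_len(length(winv))) {
      if (dir > 0 && j2 >= j0) next
      if (dir < 0 && j2 <= j0) next
      if (is.na(pair_e(mirv[i2], winv[j2], model))) next
      sub <- enum_chains(mirv, winv, i2, j2, dir, model)
      for (s in sub) out <- c(out, list(rbind(c(i2, j2), s)))
    }
  }
  out
}

# exhaustive minimum co-fold energy with the forced seed block; NA when the
# anchor is not a Watson-Crick seed match
enum_cofold_min <- function(mir, win, anchor, seed_start, seed_len, model) {
  mirv <- strsplit(mir, "")[[1]]; winv <- strsplit(win, "")[[1]]
  seed_pairs <- cbind(seed_start:(seed_start + seed_len - 1),
                      (anchor + seed_len - 1):anchor)
  for (t in seq_len(seed_len)) {
    a <- mirv[seed_pairs[t, 1]]; b <- winv[seed_pairs[t, 2]]
    pe <- pair_e(a, b, model)
    if (is.na(pe) || paste0(a, b) %in% c("GU", "UG")) return(NA_real_)
  }
  left <- enum_chains(mirv, winv, seed_start, anchor + seed_len - 1, -1, model)
  right <- enum_chains(mirv, winv, seed_start + seed_len - 1, anchor, 1, model)
  best <- Inf
  for (l in left) for (r in right) {
    e <- energy_of_structure(rbind(seed_pairs, l, r), mirv, winv, model)
    if (e < best) best <- e
  }
  best
}

# random short miRNA/window pair with a planted Watson-Crick seed anchor
random_duplex_case <- function(seed_len = 3) {
  ab <- c("A", "C", "G", "U")
  M <- sample((seed_len + 2):8, 1)
  Tn <- sample((seed_len):8, 1)
  mir <- paste(sample(ab, M, replace = TRUE), collapse = "")
  seed <- substr(mir, 2, 1 + seed_len)
  if (grepl("[^ACGU]", seed)) return(NULL)
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(seed, "")[[1]]),
                                     collapse = ""))
  anchor <- sample.int(max(1, Tn - seed_len + 1), 1)
  win <- sample(ab, max(Tn, anchor + seed_len - 1), replace = TRUE)
  win[anchor:(anchor + seed_len - 1)] <- strsplit(rc, "")[[1]]
  list(mir = mir, win = paste(win, collapse = ""), anchor = anchor,
       seed_len = seed_len)
}

# small, fast synthetic configuration used across tests
small_config <- function(seed = 17, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_true_peaks = 60, n_background_genes = 80,
         n_decoys_per_replicate = 5),
    list(...))
  do.call(synthetic_config, args)
}
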