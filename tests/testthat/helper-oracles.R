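# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# textbook BH step-up: q_(i) = min over j >= i of p_(j) * n / j
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# hypergeometric upper tail P(X >= k) by direct enumeration of dhyper terms
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(stats::dhyper(k:hi, K, N - K, n))
}

# TOM by an explicit triple loop
tom_oracle <- function(a) {
  a <- as.matrix(a)
  diag(a) <- 0
  nn <- nrow(a)
  k <- rowSums(a)
  tm <- matrix(0, nn, nn)
  for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (i == j) { tm[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(nn)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tm[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tm
}

# insulation raw window sums by an explicit double loop (0-based bin ids)
insulation_oracle <- function(m, w) {
  n <- nrow(m)
  raw <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    lo <- b - w; hi <- b + w
    if (lo < 1 || hi > n) next
    tot <- 0
    for (i in (b - w):(b - 1)) for (j in (b + 1):(b + w))
      tot <- tot + m[i, j]
    raw[b] <- tot / (w * w)
  }
  log2(raw / mean(raw, na.rm = TRUE))
}

# connected components by breadth-first search on an undirected edge list
bfs_components_oracle <- function(ids, src, dst) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (e in seq_along(src)) {
    adj[[src[e]]] <- c(adj[[src[e]]], dst[e])
    adj[[dst[e]]] <- c(adj[[dst[e]]], src[e])
  }
  seen <- character(0)
  ncomp <- 0L
  for (v in ids) {
    if (v %in% seen) next
    ncomp <- ncomp + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% seen) next
      seen <- c(seen, u)
      queue <- c(queue, setdiff(adj[[u]], seen))
    }
  }
  ncomp
}

# linear scan for TADs containing a position
locate_oracle <- function(tads, chrom, pos) {
  hits <- integer(0)
  for (i in seq_len(nrow(tads)))
    if (tads$chrom[i] == chrom && tads$start_bp[i] <= pos &&
        pos < tads$end_bp[i])
      hits <- c(hits, i)
  hits
}

# small paired count matrix with explicit values
toy_count_matrix <- function(counts, n_patients = ncol(counts) / 2) {
  patient <- rep(paste0("P", seq_len(n_patients)), each = 2)
  condition <- rep(c("normal", "lesion"), n_patients)
  ids <- paste0(patient, "_", condition)
  colnames(counts) <- ids
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  count_matrix(counts,
               data.frame(sample = ids, patient = patient,
                          condition = condition),
               stats::setNames(rep("mRNA", nrow(counts)),
                               rownames(counts)))
}

# boundary F1 with +/- tol bin tolerance
boundary_f1 <- function(called, truth, tol = 1) {
  if (!length(truth)) return(NA_real_)
  rec <- mean(vapply(truth, function(t) any(abs(called - t) <= tol), TRUE))
  prec <- if (length(called))
    mean(vapply(called, function(c) any(abs(truth - c) <= tol), TRUE))
  else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  unname(tools::md5sum(files))
}
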