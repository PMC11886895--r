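# Independent brute-force oracles. These deliberately use the naive
# definition of each quantity (all-pairs loops, exhaustive enumeration) and
# share no code with the implementations they check.

# all-pairs set-intersection enumeration of competitive pairs
oracle_pairs <- function(circ_map, gene_map, min_shared) {
  rows <- list()
  for (ci in names(circ_map)) {
    for (gi in names(gene_map)) {
      shared <- intersect(circ_map[[ci]], gene_map[[gi]])
      if (length(shared) >= min_shared) {
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = ci, gene_id = gi, n_shared = length(shared),
          shared_mirnas = paste(sort(shared), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(circ_id = character(), gene_id = character(),
               n_shared = integer(), shared_mirnas = character(),
               stringsAsFactors = FALSE))))
  out <- out[order(out$circ_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_maps <- function(n_circ, n_mirna, n_gene, edge_prob) {
  mir <- sprintf("m%03d", seq_len(n_mirna))
  pick <- function(n, prefix) {
    out <- lapply(seq_len(n), function(i) mir[runif(n_mirna) < edge_prob])
    names(out) <- sprintf("%s%03d", prefix, seq_len(n))
    out[lengths(out) > 0]
  }
  list(circ = pick(n_circ, "c"), gene = pick(n_gene, "g"))
}

# brute-force variant mapping: distance-sorted window hits union per-side top-k
oracle_map_variant <- function(variant, features, window_bp, k) {
  rows <- list()
  for (ft in unique(features$feature_type)) {
    f <- features[features$feature_type == ft & features$chrom == variant$chrom, ,
                  drop = FALSE]
    if (!nrow(f)) next
    pos <- variant$pos
    inside <- f$start <= pos & pos < f$end
    d <- ifelse(inside, 0L, pmin(abs(pos - (f$end - 1L)), abs(pos - f$start)))
    keep <- d <= window_bp
    left <- which(f$end <= pos & !inside)
    right <- which(f$start > pos & !inside)
    for (side in list(left, right)) {
      if (length(side)) {
        ord <- side[order(d[side], f$start[side], f$id[side])]
        keep[utils::head(ord, k)] <- TRUE
      }
    }
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = variant$rsid, feature_id = f$id[keep], feature_type = ft,
        relation = ifelse(inside[keep], "inside",
                          ifelse(d[keep] <= window_bp, "within_window",
                                 "closest_rank_k")),
        distance_bp = as.integer(d[keep]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(rsid = character(), feature_id = character(),
               feature_type = character(), relation = character(),
               distance_bp = integer(), stringsAsFactors = FALSE))))
  out[order(out$feature_type, out$distance_bp, out$feature_id), , drop = FALSE]
}

random_features <- function(n, chrom = "chr1", max_pos = 100000L) {
  start <- sample.int(max_pos, n)
  len <- sample.int(5000L, n)
  data.frame(id = sprintf("f%03d", seq_len(n)),
             feature_type = sample(c("circRNA", "gene"), n, replace = TRUE),
             chrom = chrom, start = start, end = start + len,
             strand = ".", stringsAsFactors = FALSE)
}

# literal step-up definition: adj_(i) = min_{j >= i} m * p_(j) / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# exhaustive enumeration of all C(N, n) draws
oracle_hyper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# betweenness via explicit all-pairs shortest-path counting
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sig <- rep(0, n)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (is.infinite(d[v])) {
            d[v] <- d[u] + 1
            nxt <- c(nxt, v)
          }
          if (d[v] == d[u] + 1) sig[v] <- sig[v] + sig[u]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sig
  }
  bw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && is.finite(dist[s, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bw
}

# exact one-sided permutation null of the Mann-Whitney U statistic
oracle_mw_p <- function(x, y) {
  vals <- c(x, y)
  m <- length(x)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(vals), m)
  us <- apply(splits, 2, function(ix) u_of(vals[ix], vals[-ix]))
  mean(us >= u_obs - 1e-9)
}

# bipartite edge list -> adjacency matrix + id order matching node tables
bipartite_adj <- function(edges) {
  circ <- sort(unique(edges$circ_id))
  gene <- sort(unique(edges$gene_id))
  ids <- c(circ, gene)
  n <- length(ids)
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    a <- edges$circ_id[i]; b <- edges$gene_id[i]
    adj[a, b] <- 1L; adj[b, a] <- 1L
  }
  adj
}

random_pair_edges <- function(n_circ, n_gene, edge_prob) {
  grid <- expand.grid(circ_id = sprintf("c%02d", seq_len(n_circ)),
                      gene_id = sprintf("g%02d", seq_len(n_gene)),
                      stringsAsFactors = FALSE)
  e <- grid[runif(nrow(grid)) < edge_prob, , drop = FALSE]
  e$n_shared <- 3L
  e$shared_mirnas <- "m1,m2,m3"
  rownames(e) <- NULL
  e
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
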