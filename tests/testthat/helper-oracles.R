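# Shared fixtures and brute-force oracles, all independent of the package's
# implementation paths they are used to check.

test_layout <- function(n_chrom = 3, len = 1e6) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom))
}

random_peaks <- function(n, layout = test_layout(), max_len = 5000,
                         cell_type = NA, cohort = NA) {
  L <- unclass(layout)
  chrom <- sample(names(L), n, replace = TRUE)
  len <- sample(50:max_len, n, replace = TRUE)
  start <- floor(runif(n) * (L[chrom] - len))
  peak_set(chrom, start, start + len, cell_type = cell_type,
           cohort = cohort, layout = layout)
}

# O(n*m) all-pairs overlap scan
oracle_overlap_any <- function(query, reference, min_bp = 1) {
  vapply(seq_len(nrow(query)), function(i) {
    any(reference$chrom == query$chrom[i] &
          pmin(reference$end, query$end[i]) -
          pmax(reference$start, query$start[i]) >= min_bp)
  }, logical(1))
}

oracle_intersect_count <- function(query, reference, min_bp = 1) {
  sum(oracle_overlap_any(query, reference, min_bp))
}

# linear-scan nearest anchor with lexicographic tie-break
oracle_nearest <- function(peaks, anchors) {
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- data.frame(distance = rep(NA_real_, nrow(peaks)),
                    id = rep(NA_character_, nrow(peaks)))
  for (i in seq_len(nrow(peaks))) {
    a <- anchors[anchors$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(a)) next
    d <- abs(mid[i] - a$pos)
    cand <- which(d == min(d))
    j <- cand[order(a$id[cand])][1L]
    raw <- mid[i] - a$pos[j]
    out$distance[i] <- if (a$strand[j] == "-") -raw else raw
    out$id[i] <- a$id[j]
  }
  out
}

# exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins (probabilities via lchoose)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c                 # total "specific"
  k <- b                     # size of group 1
  n_tot <- b + d
  lo <- max(0L, k - (n_tot - m))
  hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n_tot - m, k - x) - lchoose(n_tot, k)
  p_obs <- logp[x == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# brute-force node statistics: all-pairs BFS plus shortest-path counting
oracle_node_stats <- function(adj) {
  n <- length(adj)
  bfs <- function(s) {
    dist <- rep(-1L, n); sigma <- rep(0, n)
    dist[s] <- 0L; sigma[s] <- 1
    q <- s
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; q <- c(q, w) }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    list(dist = dist, sigma = sigma)
  }
  B <- lapply(seq_len(n), bfs)
  stress <- rep(0, n); btw <- rep(0, n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    d_st <- B[[s]]$dist[t]
    sig_st <- B[[s]]$sigma[t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (B[[s]]$dist[v] + B[[t]]$dist[v] == d_st) {
        through <- B[[s]]$sigma[v] * B[[t]]$sigma[v]
        stress[v] <- stress[v] + through
        btw[v] <- btw[v] + through / sig_st
      }
    }
  }
  data.frame(
    degree = lengths(adj),
    stress = stress,
    betweenness = btw / ((n - 1) * (n - 2) / 2),
    eccentricity = vapply(B, function(b) max(b$dist), integer(1)),
    avg_shortest_path = vapply(B, function(b) sum(b$dist) / (n - 1),
                               numeric(1))
  )
}

igraph_to_adj <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  adj
}

# connected Erdos-Renyi-style random graph with named vertices
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# exact two-sided signed-rank p by full enumeration of sign assignments
oracle_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  # the absolute-deviation event already covers both tails
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu)))
}

# independent re-implementation of the feature-priority table
oracle_classify <- function(peaks, models, promoter_window = 4000,
                            tts_window = 1000) {
  mid <- floor((peaks$start + peaks$end) / 2)
  anchors <- data.frame(chrom = models$chrom, pos = models$tss,
                        strand = models$strand, id = models$gene_id)
  nd <- oracle_nearest(peaks, anchors)
  cat_out <- rep("intergenic", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (is.na(nd$distance[i])) next
    g <- which(models$gene_id == nd$id[i])
    if (abs(nd$distance[i]) <= promoter_window) {
      cat_out[i] <- "promoter-TSS"
    } else if (abs(mid[i] - models$tes[g]) <= tts_window) {
      cat_out[i] <- "TTS"
    } else {
      es <- models$exon_starts[[g]]; ee <- models$exon_ends[[g]]
      lo <- min(models$tss[g], models$tes[g])
      hi <- max(models$tss[g], models$tes[g])
      if (length(es) && any(mid[i] >= es & mid[i] < ee)) {
        cat_out[i] <- "exon"
      } else if (mid[i] >= lo && mid[i] < hi) {
        cat_out[i] <- "intron"
      }
    }
  }
  cat_out
}

# small random gene-model table
random_genes <- function(n, layout = test_layout(), spacing = 30000) {
  L <- unclass(layout)
  per <- split(seq_len(n), rep(names(L), length.out = n))
  rows <- list()
  for (ch in names(per)) {
    k <- length(per[[ch]])
    tss <- sort(sample(seq(50000, L[[ch]] - 50000, by = spacing), k))
    for (j in seq_len(k)) {
      i <- per[[ch]][j]
      strand <- sample(c("+", "-"), 1)
      glen <- sample(4000:20000, 1)
      tes <- if (strand == "+") tss[j] + glen else tss[j] - glen
      lo <- min(tss[j], tes); hi <- max(tss[j], tes)
      cuts <- sort(sample(seq(lo, hi - 1), 6))
      rows[[i]] <- list(id = sprintf("g%03d", i), chrom = ch,
                        strand = strand, tss = tss[j], tes = tes,
                        es = cuts[c(1, 3, 5)], ee = cuts[c(2, 4, 6)])
    }
  }
  gene_models(vapply(rows, `[[`, "", "id"),
              vapply(rows, `[[`, "", "chrom"),
              vapply(rows, `[[`, "", "strand"),
              vapply(rows, `[[`, 0, "tss"),
              vapply(rows, `[[`, 0, "tes"),
              lapply(rows, `[[`, "es"),
              lapply(rows, `[[`, "ee"))
}
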