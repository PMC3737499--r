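# Independent naive re-implementations used as oracles. These are written
# from the feature definitions (published scale tables, plain loops), not
# from the package internals.

ORACLE_KD <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)
ORACLE_ZIM <- c(
  A = 0.00, R = 52.00, N = 3.38, D = 49.70, C = 1.48, Q = 3.53, E = 49.90,
  G = 0.00, H = 51.60, I = 0.13, L = 0.13, K = 49.50, M = 1.43, F = 0.35,
  P = 1.58, S = 1.67, T = 1.66, W = 2.10, Y = 1.61, V = 0.13, X = 0
)
ORACLE_AA <- c("A","C","D","E","F","G","H","I","K","L",
               "M","N","P","Q","R","S","T","V","W","Y")

rand_seq <- function(len, with_x = FALSE, cys_rich = FALSE) {
  alpha <- ORACLE_AA
  prob <- rep(1, 20)
  if (cys_rich) prob[alpha == "C"] <- 4
  if (with_x) { alpha <- c(alpha, "X"); prob <- c(prob, 0.5) }
  paste(sample(alpha, len, replace = TRUE, prob = prob), collapse = "")
}

# single-pass naive recomputation of the full feature catalogue
naive_features <- function(s, window = 5) {
  ch <- unlist(strsplit(s, ""))
  L <- length(ch)
  nk <- length(ch[ch != "X"]); if (nk == 0) nk <- 1
  out <- c()

  cpos <- c(); for (i in 1:L) if (ch[i] == "C") cpos <- c(cpos, i)
  gaps <- c(); if (length(cpos) > 1) for (k in 2:length(cpos)) gaps <- c(gaps, cpos[k] - cpos[k - 1])
  out["cys_count"] <- length(cpos)
  out["cys_fraction"] <- length(cpos) / nk
  out["n_gaps"] <- length(gaps)
  out["gap_min"] <- if (length(gaps)) min(gaps) else 0
  out["gap_max"] <- if (length(gaps)) max(gaps) else 0
  out["gap_mean"] <- if (length(gaps)) sum(gaps) / length(gaps) else 0
  out["spaced_cys_pairs"] <- length(gaps[gaps >= 3])
  out["has_cterm_cys"] <- if (length(cpos) && max(cpos) > L - 3) 1 else 0

  nb <- length(ch[ch == "K"]) + length(ch[ch == "R"])
  na_ <- length(ch[ch == "D"]) + length(ch[ch == "E"])
  out["basic_fraction"] <- nb / nk
  out["acidic_fraction"] <- na_ / nk
  out["his_fraction"] <- length(ch[ch == "H"]) / nk
  out["net_charge"] <- nb - na_
  out["charged_fraction"] <- (nb + na_) / nk

  for (scale_name in c("kd", "zim")) {
    sc <- if (scale_name == "kd") ORACLE_KD else ORACLE_ZIM
    v <- as.numeric(sc[ch])
    wm <- c()
    if (L < window) wm <- mean(v) else
      for (i in 1:(L - window + 1)) wm <- c(wm, mean(v[i:(i + window - 1)]))
    out[paste0(scale_name, "_mean")] <- mean(wm)
    out[paste0(scale_name, "_sd")] <- if (length(wm) > 1) sd(wm) else 0
    out[paste0(scale_name, "_max")] <- max(wm)
    out[paste0(scale_name, "_min")] <- min(wm)
    out[paste0(scale_name, "_nterm_mean")] <- mean(v[1:min(20, L)])
    out[paste0(scale_name, "_mature_mean")] <- if (L > 20) mean(v[21:L]) else 0
  }

  for (a in ORACLE_AA) out[paste0("freq_", a)] <- length(ch[ch == a]) / nk
  out["aromatic_fraction"] <- sum(out[c("freq_F", "freq_W", "freq_Y")])
  out["small_fraction"] <- sum(out[c("freq_A", "freq_G", "freq_S", "freq_T")])
  out["length"] <- L
  out["log_length"] <- log(L)
  out
}

# exhaustive window-enumeration oracle for the scaffold detector
naive_scaffold <- function(s, min_cys = 8, max_cys = 12,
                           min_len = 60, max_len = 95, max_free = 30) {
  ch <- unlist(strsplit(s, ""))
  L <- length(ch)
  cand <- data.frame()
  for (st in seq_len(L)) {
    if (ch[st] != "C") next
    for (en in st:L) {
      if (ch[en] != "C") next
      len <- en - st + 1
      if (len < min_len || len > max_len) next
      win <- ch[st:en]
      nc <- sum(win == "C")
      if (nc < min_cys || nc > max_cys) next
      runs <- rle(win == "C")
      if (any(runs$lengths[!runs$values] > max_free)) next
      cand <- rbind(cand, data.frame(start = st, end = en, n_cys = nc, len = len))
    }
  }
  picked <- data.frame()
  while (nrow(cand) > 0) {
    best <- cand[order(-cand$n_cys, cand$len, cand$start), ][1, ]
    picked <- rbind(picked, best)
    cand <- cand[cand$end < best$start | cand$start > best$end, , drop = FALSE]
  }
  if (nrow(picked) == 0) return(picked)
  picked[order(picked$start), c("start", "end", "n_cys")]
}

# O(n^2) transitive-closure oracle for proximity clustering;
# returns a list of sorted gene-name vectors (clusters with >= min_genes)
naive_clusters <- function(loci, max_gap, min_genes) {
  n <- nrow(loci)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (loci$chromosome[i] != loci$chromosome[j]) next
    gap <- max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j]) - 1
    adj[i, j] <- max(gap, 0) <= max_gap
  }
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { k <- k + 1; comp[which(adj[i, ])] <- k }
  }
  out <- list()
  for (g in unique(comp)) {
    mem <- loci$gene[comp == g]
    if (length(mem) >= min_genes) out[[length(out) + 1]] <- sort(mem)
  }
  out[order(vapply(out, `[`, character(1), 1))]
}

# AdaBoost exponential training-error bound prod_t 2*sqrt(eps_t(1 - eps_t)),
# recovered from the stump weights (eps_t = 1 / (1 + exp(2 * alpha_t)))
boosting_bound <- function(member) {
  eps <- 1 / (1 + exp(2 * member$stumps$alpha))
  cumprod(2 * sqrt(eps * (1 - eps)))
}

# membership sets from find_clusters output, in comparable form
cluster_sets <- function(clusters) {
  out <- lapply(clusters$members, sort)
  out[order(vapply(out, `[`, character(1), 1))]
}
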