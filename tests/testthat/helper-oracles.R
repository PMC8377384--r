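# Independent literal-summation oracles. These deliberately re-derive every
# quantity with explicit loops from the raw property tables, sharing no code
# path with the package implementation beyond the shipped CSV constants.

ORACLE_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
ORACLE_PSSM_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Normalized lookup (X -> 0) recomputed from the raw CSV values.
oracle_norm_prop <- function(name) {
  tab <- aa_property(name)
  raw <- setNames(tab$value, tab$amino_acid)
  m <- sum(raw) / 20
  s <- sqrt(sum((raw - m)^2) / 20)
  c((raw - m) / s, X = 0)
}

random_protein <- function(len, include_x = FALSE) {
  alphabet <- if (include_x) c(ORACLE_AA, "X") else ORACLE_AA
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

oracle_pseaac <- function(sequence, lambda, w = 0.05) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  props <- lapply(c("hydrophobicity", "hydrophilicity", "side_chain_mass"),
                  oracle_norm_prop)
  theta <- numeric(lambda)
  if (lambda > 0) {
    for (k in 1:lambda) {
      acc <- 0
      for (i in 1:(L - k)) {
        corr <- 0
        for (p in props) corr <- corr + (p[[chars[i]]] - p[[chars[i + k]]])^2
        acc <- acc + corr / 3
      }
      theta[k] <- acc / (L - k)
    }
  }
  f <- vapply(ORACLE_AA, function(a) sum(chars == a), numeric(1))
  unname(c(f, w * theta) / (sum(f) + w * sum(theta)))
}

oracle_psepssm <- function(scores, xi) {
  L <- nrow(scores)
  p <- matrix(0, L, 20)
  for (i in 1:L) {
    m <- sum(scores[i, ]) / 20
    s <- sqrt(sum((scores[i, ] - m)^2) / 20)
    if (s > 0) p[i, ] <- (scores[i, ] - m) / s
  }
  out <- numeric(0)
  for (j in 1:20) out <- c(out, sum(p[, j]) / L)
  if (xi > 0) {
    for (g in 1:xi) {
      for (j in 1:20) {
        acc <- 0
        for (i in 1:(L - g)) acc <- acc + (p[i, j] - p[i + g, j])^2
        out <- c(out, acc / (L - g))
      }
    }
  }
  out
}

ORACLE_CLASSES <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
                       c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
                       c("R", "K"), c("D", "E"), c("C"))

oracle_rsiv <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  n_std <- sum(chars != "X")
  out <- numeric(0)
  for (nm in c("hydrophobicity", "hydrophilicity", "side_chain_volume",
               "polarity", "polarizability", "sasa")) {
    p <- oracle_norm_prop(nm)
    for (a in ORACLE_AA) out <- c(out, p[[a]] * sum(chars == a) / n_std)
  }
  cls <- function(ch) {
    for (k in 1:7) if (ch %in% ORACLE_CLASSES[[k]]) return(k)
    NA_integer_
  }
  cv <- vapply(chars, cls, integer(1))
  for (k in 1:7) out <- c(out, sum(cv == k, na.rm = TRUE) / n_std)
  for (c1 in 1:7) for (c2 in 1:7) {
    acc <- 0
    for (i in 1:(L - 1)) {
      if (!is.na(cv[i]) && !is.na(cv[i + 1]) && cv[i] == c1 && cv[i + 1] == c2) acc <- acc + 1
    }
    out <- c(out, acc / (L - 1))
  }
  for (c1 in 1:6) for (c2 in (c1 + 1):7) {
    acc <- 0
    for (i in 1:(L - 1)) {
      if (!is.na(cv[i]) && !is.na(cv[i + 1]) &&
          ((cv[i] == c1 && cv[i + 1] == c2) || (cv[i] == c2 && cv[i + 1] == c1))) acc <- acc + 1
    }
    out <- c(out, acc / (L - 1))
  }
  out
}

oracle_ad <- function(sequence, lag) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  prop_names <- c("hydrophobicity", "hydrophilicity", "side_chain_volume",
                  "polarity", "polarizability", "sasa", "net_charge_index")
  mba <- ma <- ga <- c()
  for (nm in prop_names) {
    pv <- oracle_norm_prop(nm)
    x <- unname(vapply(chars, function(ch) pv[[ch]], numeric(1)))
    xb <- sum(x) / L
    ss <- sum((x - xb)^2)
    for (d in 1:lag) {
      s1 <- s2 <- s3 <- 0
      for (i in 1:(L - d)) {
        s1 <- s1 + x[i] * x[i + d]
        s2 <- s2 + (x[i] - xb) * (x[i + d] - xb)
        s3 <- s3 + (x[i] - x[i + d])^2
      }
      mba <- c(mba, s1 / (L - d))
      ma <- c(ma, if (ss > 0) (s2 / (L - d)) / (ss / L) else 0)
      ga <- c(ga, if (ss > 0) (s3 / (2 * (L - d))) / (ss / (L - 1)) else 0)
    }
  }
  c(mba, ma, ga)
}

# Normalized Mann-Whitney U by brute-force pair counting (ties count 1/2).
oracle_auroc <- function(y, scores) {
  pos <- which(y == 1); neg <- which(y == 0)
  acc <- 0
  for (i in pos) for (j in neg) {
    acc <- acc + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

# Literal single boosting step with a depth-1 stump: exhaustive split search
# minimizing residual SSE, Newton leaf values, shrunken additive update.
oracle_gtb_one_step <- function(x, y, learning_rate) {
  n <- nrow(x)
  f0 <- log(mean(y) / (1 - mean(y)))
  p <- rep(1 / (1 + exp(-f0)), n)
  r <- y - p
  best <- list(sse = Inf)
  for (j in seq_len(ncol(x))) {
    cuts <- sort(unique(x[, j]))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (cut in mids) {
      left <- x[, j] < cut
      sse <- sum((r[left] - mean(r[left]))^2) + sum((r[!left] - mean(r[!left]))^2)
      if (sse < best$sse - 1e-12) best <- list(sse = sse, j = j, cut = cut, left = left)
    }
  }
  gam_l <- sum(r[best$left]) / sum(p[best$left] * (1 - p[best$left]))
  gam_r <- sum(r[!best$left]) / sum(p[!best$left] * (1 - p[!best$left]))
  f1 <- f0 + learning_rate * ifelse(best$left, gam_l, gam_r)
  list(f0 = f0, scores = f1, split_feature = best$j, cut = best$cut)
}
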