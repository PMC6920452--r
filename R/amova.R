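# sums of squared deviations from pairwise (squared) distances:
# SSD(S) = sum_{i<j in S} d2[i,j] / |S|   (Excoffier et al. 1992)
ssd_within <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx]) / 2 / length(idx)
}

#' Pairwise Phi-ST between two populations
#'
#' Distance-based fixation index from the two-population AMOVA on squared
#' pairwise differences: `Phi_ST = sigma2_among / sigma2_total`.
#' Significance is assessed by permuting individuals between the two
#' populations and counting how often the permuted Phi-ST is `>=` the
#' observed one. With all between-haplotype distances equal (0/1), the
#' statistic reduces to the classical frequency-based F-ST.
#'
#' @param d2 symmetric matrix of squared molecular distances between
#'   individuals (for sequences, the number of differing sites is used
#'   directly, the convention of distance-based AMOVA).
#' @param pop factor/character of population membership, one entry per row
#'   of `d2` (exactly two levels used here).
#' @param n_perm permutations for the P-value (default 10000; 0 skips it).
#' @param seed optional integer seed.
#' @return named numeric vector `c(phist, p)` (`p` is `NA` when
#'   `n_perm = 0`).
#' @export
pairwise_phist <- function(d2, pop, n_perm = 10000L, seed = NULL) {
  pop <- as.factor(droplevels(as.factor(pop)))
  stopifnot(nlevels(pop) == 2L, nrow(d2) == length(pop))
  sizes <- table(pop)
  if (any(sizes < 2))
    warning("population(s) of size < 2: ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            "; Phi-ST still computed")

  phist_of <- function(pp) {
    idx <- split(seq_along(pp), pp)
    N <- length(pp); P <- length(idx)
    ssd_t <- sum(d2) / 2 / N
    ssd_w <- sum(vapply(idx, function(i) ssd_within(d2, i), numeric(1)))
    ssd_a <- ssd_t - ssd_w
    df_a <- P - 1; df_w <- N - P
    if (df_w == 0) return(NA_real_)
    msd_w <- ssd_w / df_w
    n0 <- (N - sum(lengths(idx)^2) / N) / df_a
    s2_a <- (ssd_a / df_a - msd_w) / n0
    tot <- s2_a + msd_w
    if (tot == 0) 0 else s2_a / tot
  }

  obs <- phist_of(pop)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- replicate(n_perm, phist_of(sample(pop)))
    p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  }
  c(phist = obs, p = p)
}

#' Pairwise Phi-ST matrix over all populations
#'
#' @inheritParams pairwise_phist
#' @param pop factor/character of population membership (any number of
#'   levels).
#' @return list with symmetric matrices `phist` and `p`.
#' @export
pairwise_phist_matrix <- function(d2, pop, n_perm = 10000L, seed = NULL) {
  pop <- droplevels(as.factor(pop))
  lv <- levels(pop)
  K <- length(lv)
  ph <- pv <- matrix(NA_real_, K, K, dimnames = list(lv, lv))
  diag(ph) <- 0; diag(pv) <- 1
  if (!is.null(seed)) set.seed(seed)
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    sel <- pop %in% lv[c(a, b)]
    r <- suppressWarnings(
      pairwise_phist(d2[sel, sel, drop = FALSE], pop[sel], n_perm))
    ph[a, b] <- ph[b, a] <- r[["phist"]]
    pv[a, b] <- pv[b, a] <- r[["p"]]
  }
  list(phist = ph, p = pv)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level decomposition of squared pairwise molecular distances into
#' variance among groups, among populations within groups, and within
#' populations (Excoffier-style sums of squares), with Phi-statistics and
#' permutation P-values. Negative variance components are reported as
#' computed (flagged, not truncated), which keeps the percentage
#' decomposition algebraically consistent. With a single group the
#' decomposition collapses to the two-level design.
#'
#' Permutation scheme: `Phi_ST` permutes individuals across populations;
#' `Phi_CT` permutes whole populations across groups; `Phi_SC` permutes
#' individuals across populations within their group.
#'
#' @param d2 symmetric matrix of squared molecular distances between
#'   individuals.
#' @param pop population membership, one entry per individual.
#' @param group optional named vector mapping population -> group; `NULL`
#'   gives the two-level design.
#' @param n_perm permutations per Phi-statistic (default 10000; 0 skips).
#' @param seed optional integer seed.
#' @return object of class `amova_result`: data.frame `components`
#'   (source, df, SSD, variance, percent), `phi` (named vector), `p`
#'   (permutation P-values), `negative_components` flag.
#' @export
amova <- function(d2, pop, group = NULL, n_perm = 10000L, seed = NULL) {
  pop <- droplevels(as.factor(pop))
  stopifnot(nrow(d2) == length(pop), ncol(d2) == length(pop))
  two_level <- is.null(group)
  if (two_level) group <- stats::setNames(rep("all", nlevels(pop)),
                                          levels(pop))
  if (!all(levels(pop) %in% names(group)))
    stop("group map missing population(s): ",
         paste(setdiff(levels(pop), names(group)), collapse = ", "))
  grp_of_pop <- group[levels(pop)]
  if (any(table(grp_of_pop) == 1L) && !two_level)
    warning("singleton group(s): ",
            paste(names(which(table(grp_of_pop) == 1L)), collapse = ", "),
            "; their among-populations-within-group component is degenerate")

  decomp <- function(pp, grp_map) {
    idx_pop <- split(seq_along(pp), pp)
    idx_pop <- idx_pop[lengths(idx_pop) > 0]
    pops <- names(idx_pop)
    gg <- grp_map[pops]
    N <- length(pp); P <- length(pops); G <- length(unique(gg))
    ssd_t <- sum(d2[seq_len(N), seq_len(N)]) / 2 / N  # pp indexes all rows

    ssd_wp <- sum(vapply(idx_pop, function(i) ssd_within(d2, i),
                         numeric(1)))
    idx_grp <- lapply(split(pops, gg), function(ps)
      unlist(idx_pop[ps], use.names = FALSE))
    ssd_wg <- sum(vapply(idx_grp, function(i) ssd_within(d2, i),
                         numeric(1)))
    ssd_ap <- ssd_wg - ssd_wp   # among populations within groups
    ssd_ag <- ssd_t - ssd_wg    # among groups

    n_p <- lengths(idx_pop); n_g <- lengths(idx_grp)
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    msd_wp <- if (df_wp > 0) ssd_wp / df_wp else 0
    s2_c <- msd_wp

    sum_np2_by_g <- vapply(split(n_p, gg), function(v) sum(v^2), numeric(1))
    n1 <- if (df_ap > 0)
      (N - sum(sum_np2_by_g / n_g[names(sum_np2_by_g)])) / df_ap else NA
    s2_b <- if (df_ap > 0) (ssd_ap / df_ap - s2_c) / n1 else 0
    if (df_ag > 0) {
      n2 <- (sum(sum_np2_by_g / n_g[names(sum_np2_by_g)]) -
               sum(n_p^2) / N) / df_ag
      n3 <- (N - sum(n_g^2) / N) / df_ag
      s2_a <- (ssd_ag / df_ag - s2_c - n2 * s2_b) / n3
    } else s2_a <- 0
    list(ssd = c(ag = ssd_ag, ap = ssd_ap, wp = ssd_wp, t = ssd_t),
         df = c(ag = df_ag, ap = df_ap, wp = df_wp, t = N - 1),
         s2 = c(a = s2_a, b = s2_b, c = s2_c))
  }

  obs <- decomp(pop, group)
  s2 <- obs$s2; tot <- sum(s2)
  phi <- c(
    phi_st = if (tot != 0) (s2[["a"]] + s2[["b"]]) / tot else 0,
    phi_ct = if (tot != 0) s2[["a"]] / tot else 0,
    phi_sc = if ((s2[["b"]] + s2[["c"]]) != 0)
      s2[["b"]] / (s2[["b"]] + s2[["c"]]) else 0)

  p <- c(phi_st = NA_real_, phi_ct = NA_real_, phi_sc = NA_real_)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    grp_of_ind <- group[as.character(pop)]
    perm_st <- perm_ct <- perm_sc <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      # Phi_ST: individuals shuffled across everything
      d1 <- decomp(sample(pop), group)
      perm_st[k] <- if (sum(d1$s2) != 0)
        (d1$s2[["a"]] + d1$s2[["b"]]) / sum(d1$s2) else 0
      # Phi_CT: population labels shuffled across groups
      g2 <- stats::setNames(sample(unname(group[levels(pop)])), levels(pop))
      d2c <- decomp(pop, g2)
      perm_ct[k] <- if (sum(d2c$s2) != 0) d2c$s2[["a"]] / sum(d2c$s2) else 0
      # Phi_SC: individuals shuffled among populations within their group
      pp <- as.character(pop)
      for (g in unique(grp_of_ind)) {
        sel <- grp_of_ind == g
        pp[sel] <- sample(pp[sel])
      }
      d3 <- decomp(factor(pp, levels = levels(pop)), group)
      perm_sc[k] <- if ((d3$s2[["b"]] + d3$s2[["c"]]) != 0)
        d3$s2[["b"]] / (d3$s2[["b"]] + d3$s2[["c"]]) else 0
    }
    p <- c(phi_st = (sum(perm_st >= phi[["phi_st"]]) + 1) / (n_perm + 1),
           phi_ct = (sum(perm_ct >= phi[["phi_ct"]]) + 1) / (n_perm + 1),
           phi_sc = (sum(perm_sc >= phi[["phi_sc"]]) + 1) / (n_perm + 1))
  }

  comp <- data.frame(
    source = c("among groups", "among populations within groups",
               "within populations", "total"),
    df = obs$df[c("ag", "ap", "wp", "t")],
    SSD = obs$ssd[c("ag", "ap", "wp", "t")],
    variance = c(s2[["a"]], s2[["b"]], s2[["c"]], tot),
    percent = if (tot != 0)
      c(s2[["a"]], s2[["b"]], s2[["c"]], tot) / tot * 100 else
        c(0, 0, 0, 0),
    row.names = NULL)
  if (two_level) comp <- comp[-1, , drop = FALSE]

  structure(list(components = comp, phi = phi, p = p,
                 negative_components = any(s2 < 0),
                 n_perm = n_perm, two_level = two_level),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Analysis of molecular variance",
      if (x$two_level) "(two-level)\n" else "(three-level)\n")
  print(x$components, digits = 4, row.names = FALSE)
  cat("\nPhi statistics:\n")
  ph <- data.frame(statistic = names(x$phi), value = unname(x$phi),
                   p = unname(x$p))
  if (x$two_level) ph <- ph[ph$statistic == "phi_st", , drop = FALSE]
  print(ph, digits = 4, row.names = FALSE)
  if (x$negative_components)
    cat("note: negative variance component(s) reported as computed\n")
  invisible(x)
}

#' Squared pairwise-difference distances between individuals
#'
#' Expands a haplotype catalog into the individual-level matrix of
#' pairwise difference counts (number of differing sites), the distance
#' convention of distance-based AMOVA.
#'
#' @param catalog a [call_haplotypes()] result.
#' @return symmetric integer matrix, one row per sequence (ids as
#'   dimnames), in the order of `catalog$members`.
#' @export
catalog_pairwise_differences <- function(catalog) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  hd <- pairwise_distance_matrix(catalog$haplotypes) * catalog$seq_length
  lab <- catalog$members
  d <- hd[lab, lab, drop = FALSE]
  dimnames(d) <- list(names(lab), names(lab))
  d
}
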