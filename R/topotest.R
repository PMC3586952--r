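## Constrained alternative topologies and the eight resampling tests on
## per-site log-likelihood matrices (AU, NP, BP, PP, KH, SH, WKH, WSH), with
## confidence sets. The tests operate on RELL replicates: per-site
## log-likelihoods are resampled with replacement without re-optimizing.

TOPOTEST_NAMES <- c("AU", "NP", "BP", "PP", "KH", "SH", "WKH", "WSH")

# Per-replicate winners; exact ties rotate deterministically with the
# replicate index so tied trees share the win fraction.
rell_winners <- function(R) {
  mx <- apply(R, 2, max)
  vapply(seq_len(ncol(R)), function(r) {
    w <- which(R[, r] == mx[r])
    if (length(w) == 1L) w else w[(r - 1L) %% length(w) + 1L]
  }, 1L)
}

#' Generate the twelve constrained placement hypotheses
#'
#' Prunes the focal clade (its internal structure kept intact) from a
#' species tree whose groups are monophyletic, and regrafts it at each of
#' twelve positions: sister to each single fungal group (C, Z, B, T, S, P),
#' at the common ancestor of S+P, of T+S+P (ascomycota), of B+T+S+P
#' (dikarya), of B+T+S+P+Z, basal to all fungi (A), and basal to all fungi
#' with Chytridiomycotina and Zygomycotina grouped (A-C+Z).
#'
#' @param speciesTree a \code{\linkS4class{SpeciesTree}} containing an
#'   outgroup and the six fungal groups, each monophyletic.
#' @param focalGroup focal group label.
#' @param outgroupLabel outgroup group label.
#' @return named list of twelve \code{\linkS4class{SpeciesTree}} objects.
#' @export
alternativeTopologies <- function(speciesTree, focalGroup = "Microsporidia",
                                  outgroupLabel = "Outgroup") {
  tr <- asPhylo(speciesTree)
  groups <- groupMap(speciesTree)
  tips_of <- function(gs) names(groups)[groups %in% gs]
  for (g in unique(groups)) {
    tps <- tips_of(g)
    stop_if(length(tps) > 1 && !ape::is.monophyletic(tr, tps),
            paste("group not monophyletic in input:", g))
  }
  focal_tips <- tips_of(focalGroup)
  focal_sub <- if (length(focal_tips) == 1L) {
    s <- ape::read.tree(text = paste0("(", focal_tips, ":0.05);"))
    ape::collapse.singles(s)
  } else ape::extract.clade(tr, ape::getMRCA(tr, focal_tips))
  base <- ape::drop.tip(tr, focal_tips)
  lets <- GROUP_LETTERS
  fungal_groups <- names(lets)[names(lets) %in% unique(groups)]
  targets <- list()
  for (g in fungal_groups) targets[[unname(lets[g])]] <- tips_of(g)
  targets[["S+P"]] <- tips_of(c("Saccharomycotina", "Pezizomycotina"))
  targets[["T+S+P"]] <- tips_of(c("Taphrinomycotina", "Saccharomycotina",
                                  "Pezizomycotina"))
  targets[["B+T+S+P"]] <- tips_of(c("Basidiomycotina", "Taphrinomycotina",
                                    "Saccharomycotina", "Pezizomycotina"))
  targets[["B+T+S+P+Z"]] <- tips_of(c("Zygomycotina", "Basidiomycotina",
                                      "Taphrinomycotina", "Saccharomycotina",
                                      "Pezizomycotina"))
  targets[["A"]] <- tips_of(fungal_groups)
  out <- lapply(names(targets), function(lab)
    attach_clade_at(base, focal_sub, targets[[lab]]))
  names(out) <- names(targets)
  # A-C+Z: regroup chytrids+zygomycetes, then attach basal to all fungi
  cz_base <- regroup_cz(base, tips_of("Chytridiomycotina"),
                        tips_of("Zygomycotina"))
  out[["A-C+Z"]] <- attach_clade_at(cz_base, focal_sub, targets[["A"]])
  lapply(out, function(t2) SpeciesTree(t2, groups))
}

# Attach `sub` (given a root edge) to the stem branch of the clade spanned
# by `cladeTips` in `base`, at the midpoint of that branch.
attach_clade_at <- function(base, sub, cladeTips) {
  node <- if (length(cladeTips) == 1L) match(cladeTips, base$tip.label)
    else ape::getMRCA(base, cladeTips)
  edge_i <- match(node, base$edge[, 2])
  stop_if(is.na(edge_i), "target clade has no stem edge (is it the root?)")
  len <- base$edge.length[edge_i]
  sub$root.edge <- max(len / 2, 1e-8)
  out <- ape::bind.tree(base, sub, where = node, position = len / 2)
  ape::collapse.singles(out)
}

# Move the Zygomycotina clade to be sister to the Chytridiomycotina clade.
regroup_cz <- function(base, cTips, zTips) {
  z_node <- if (length(zTips) == 1L) match(zTips, base$tip.label)
    else ape::getMRCA(base, zTips)
  z_sub <- if (length(zTips) == 1L)
    ape::collapse.singles(ape::read.tree(text = paste0("(", zTips, ":0.05);")))
  else ape::extract.clade(base, z_node)
  pruned <- ape::drop.tip(base, zTips)
  attach_clade_at(pruned, z_sub, cTips)
}

#' RELL resampling of site log-likelihoods
#'
#' Resamples \code{ceiling(scale * n_sites)} site indices with replacement
#' and returns each tree's summed log-likelihood per replicate.
#'
#' @param x a \code{\linkS4class{SiteLnLMatrix}} or trees x sites matrix.
#' @param nReps number of replicates (>= 1).
#' @param scale resampled-length multiplier (> 0).
#' @param seed integer seed.
#' @return trees x nReps matrix of replicate totals.
#' @export
rellResample <- function(x, nReps, scale = 1, seed = NULL) {
  lnl <- if (is(x, "SiteLnLMatrix")) siteLnL(x) else x
  stop_if(length(lnl) == 0L, "empty matrix")
  stop_if(nReps < 1 || scale <= 0, "nReps >= 1 and scale > 0 required")
  n <- ncol(lnl)
  nsamp <- ceiling(scale * n)
  with_seed(seed, {
    out <- matrix(NA_real_, nrow(lnl), nReps, dimnames = list(rownames(lnl), NULL))
    for (r in seq_len(nReps)) {
      counts <- tabulate(sample.int(n, nsamp, replace = TRUE), n)
      out[, r] <- lnl %*% counts
    }
    out
  })
}

#' Run the eight topology tests on a site log-likelihood matrix
#'
#' Computes, for every tree, the AU (multiscale-bootstrap with probit
#' regression), NP (smoothed bootstrap probability from the same fit), BP
#' (raw replicate win fraction), PP (posterior probability by the BIC
#' approximation), KH, SH, WKH and WSH p-values from RELL replicates. KH and
#' WKH compare each tree with the maximum-likelihood tree (the weighted
#' variant standardizes by the replicate standard error of the pairwise
#' difference); SH and WSH use worst-case centering over all trees. KH-type
#' p-values are one-sided on centered differences.
#'
#' @param x a \code{\linkS4class{SiteLnLMatrix}} or trees x sites matrix
#'   with rownames.
#' @param nReps replicates per scale.
#' @param seed integer seed.
#' @param scales relative resampling sizes for the AU multiscale fit.
#' @return a list of class \code{"topotestReport"}: \code{p} (trees x 8
#'   matrix), \code{obs} (total lnL), \code{best} (tree id),
#'   \code{nSites}, \code{nReps}.
#' @export
runTopologyTests <- function(x, nReps = 2000L, seed = NULL,
                             scales = seq(0.5, 1.4, by = 0.1)) {
  lnl <- if (is(x, "SiteLnLMatrix")) siteLnL(x) else x
  stop_if(is.null(rownames(lnl)), "matrix must have tree-id rownames")
  m <- nrow(lnl)
  ids <- rownames(lnl)
  obs <- rowSums(lnl)
  if (m == 1L) {
    p <- matrix(1, 1, length(TOPOTEST_NAMES),
                dimnames = list(ids, TOPOTEST_NAMES))
    return(structure(list(p = p, obs = obs, best = ids[1],
                          nSites = ncol(lnl), nReps = nReps),
                     class = "topotestReport"))
  }
  best <- which.max(obs)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(scales) + 1L))
  R <- rellResample(lnl, nReps, scale = 1, seed = seeds[1])
  Rc <- R - obs                      # worst-case centered replicate totals
  p <- matrix(NA_real_, m, length(TOPOTEST_NAMES),
              dimnames = list(ids, TOPOTEST_NAMES))
  # BP: replicate win fractions (exact ties rotate across replicates)
  p[, "BP"] <- tabulate(rell_winners(R), m) / nReps
  # PP: BIC-approximate posterior probabilities
  p[, "PP"] <- exp(obs - logsumexp(obs))
  # pairwise replicate sd of centered differences (for weighted tests)
  sd_pair <- matrix(1, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
    s <- stats::sd(Rc[j, ] - Rc[i, ])
    sd_pair[i, j] <- if (is.finite(s) && s > 0) s else 1e-12
  }
  for (i in seq_len(m)) {
    opp <- if (i == best) which.max(replace(obs, i, -Inf)) else best
    D <- obs[opp] - obs[i]
    delta <- Rc[opp, ] - Rc[i, ]
    p[i, "KH"] <- mean(delta >= D)
    # WKH: opponent maximizing the standardized observed difference
    stat_w <- (obs - obs[i]) / sd_pair[i, ]
    oppw <- which.max(replace(stat_w, i, -Inf))
    p[i, "WKH"] <- mean((Rc[oppw, ] - Rc[i, ]) / sd_pair[i, oppw] >=
                          (obs[oppw] - obs[i]) / sd_pair[i, oppw])
    # SH / WSH: worst-case over all candidate trees
    Dsh <- max(obs) - obs[i]
    Ssh <- apply(Rc - matrix(Rc[i, ], m, nReps, byrow = TRUE), 2, max)
    p[i, "SH"] <- mean(Ssh >= Dsh)
    w_obs <- max((obs[-i] - obs[i]) / sd_pair[i, -i])
    Sw <- apply((Rc[-i, , drop = FALSE] -
                   matrix(Rc[i, ], m - 1L, nReps, byrow = TRUE)) /
                  sd_pair[i, -i], 2, max)
    p[i, "WSH"] <- mean(Sw >= w_obs)
  }
  # AU / NP by multiscale bootstrap with WLS probit regression
  bp_scale <- matrix(NA_real_, m, length(scales))
  for (k in seq_along(scales)) {
    Rk <- rellResample(lnl, nReps, scale = scales[k], seed = seeds[k + 1L])
    bp_scale[, k] <- tabulate(rell_winners(Rk), m) / nReps
  }
  sigma <- sqrt(1 / scales)  # sigma^2 = n / n'
  for (i in seq_len(m)) {
    bp <- bp_scale[i, ]
    if (all(bp >= 1 - 1e-12)) { p[i, "AU"] <- 1; p[i, "NP"] <- 1; next }
    if (all(bp <= 1e-12)) { p[i, "AU"] <- 0; p[i, "NP"] <- 0; next }
    bpc <- pmin(pmax(bp, 1 / (2 * nReps)), 1 - 1 / (2 * nReps))
    z <- qnorm(1 - bpc)
    w <- nReps * dnorm(z)^2 / (bpc * (1 - bpc))
    X <- cbind(sigma, 1 / sigma)
    fit <- tryCatch(stats::lm.wfit(X, z, w)$coefficients,
                    error = function(e) c(NA, NA))
    if (anyNA(fit)) { p[i, "AU"] <- p[i, "NP"] <- p[i, "BP"]; next }
    d <- fit[1]; cc <- fit[2]
    p[i, "AU"] <- 1 - pnorm(d - cc)
    p[i, "NP"] <- 1 - pnorm(d + cc)
  }
  structure(list(p = p, obs = obs, best = ids[best], nSites = ncol(lnl),
                 nReps = nReps),
            class = "topotestReport")
}

#' @export
print.topotestReport <- function(x, ...) {
  cat("Topology test report:", nrow(x$p), "trees,", x$nSites, "sites,",
      x$nReps, "RELL replicates; best tree:", x$best, "\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Confidence set of topologies for one test
#'
#' Trees whose p-value under the chosen test is at least \code{alpha}; the
#' maximum-likelihood tree is always included.
#'
#' @param report a \code{\link{runTopologyTests}} report.
#' @param test one of AU, NP, BP, PP, KH, SH, WKH, WSH.
#' @param alpha significance level.
#' @return character vector of tree ids.
#' @export
confidenceSet <- function(report, test = "AU", alpha = 0.05) {
  stop_if(!test %in% colnames(report$p), paste("unknown test:", test))
  ids <- rownames(report$p)
  keep <- ids[report$p[, test] >= alpha]
  union(report$best, keep)
}

#' Read a site log-likelihood matrix
#'
#' Format: one row per tree; first field the tree id, remaining
#' whitespace-separated fields the per-site log-likelihoods.
#' @param path file path.
#' @return a \code{\linkS4class{SiteLnLMatrix}}.
#' @export
readSiteLnL <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(x) as.numeric(x[-1L]))
  stop_if(length(unique(lengths(vals))) != 1L, "unequal site counts across trees")
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  SiteLnLMatrix(m)
}

#' Write a site log-likelihood matrix
#' @param x a \code{\linkS4class{SiteLnLMatrix}}.
#' @param path file path.
#' @export
writeSiteLnL <- function(x, path) {
  lnl <- siteLnL(x)
  writeLines(vapply(seq_len(nrow(lnl)), function(i)
    paste(c(rownames(lnl)[i], format(lnl[i, ], digits = 10)), collapse = "\t"),
    ""), path)
  invisible(path)
}

#' Write a topology test report table
#'
#' Rows are hypotheses, columns the eight tests, plus the best-tree flag and
#' the retained/rejected status under each test at \code{alpha}.
#' @param report a \code{\link{runTopologyTests}} report.
#' @param path file path.
#' @param alpha significance level for the retained flag.
#' @export
writeTestReport <- function(report, path, alpha = 0.05) {
  d <- data.frame(tree = rownames(report$p), round(report$p, 6),
                  best = rownames(report$p) == report$best,
                  check.names = FALSE)
  for (t in TOPOTEST_NAMES)
    d[[paste0(t, "_retained")]] <- rownames(report$p) %in%
      confidenceSet(report, t, alpha)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
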