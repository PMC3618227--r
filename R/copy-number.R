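#' Rank-based recursive segmentation of a log-ratio profile
#'
#' Recursive binary splitting driven by a rank statistic: within each
#' candidate segment the probe values are ranked, and the boundary maximizing
#' the standardized rank-sum difference between the left and right parts is
#' proposed as a changepoint. The split is accepted when its permutation
#' p-value (max statistic over boundaries, probe order shuffled) falls below
#' `alpha`; accepted splits recurse into both halves. Segments inherit the
#' mean log2 ratio of their probes. Using ranks rather than means makes the
#' procedure robust to heavy-tailed probe noise, in the spirit of
#' rank-segmentation methods used for aCGH profiles.
#'
#' @param probes data frame with columns `chrom`, `start`, `end`, `log2`
#'   (sorted by position within chromosome).
#' @param min_probes minimum probes per segment (>= 2).
#' @param alpha permutation p-value needed to accept a split.
#' @param permutations number of permutations per tested split.
#' @param seed RNG seed for the permutation test (local; the caller's RNG
#'   state is restored).
#' @return data frame of segments: `chrom`, `start`, `end`, `n_probes`,
#'   `seg_mean`.
#' @export
segment_profile <- function(probes, min_probes = 5, alpha = 0.01,
                            permutations = 1000, seed = 1L) {
  stopifnot(min_probes >= 2, alpha > 0, alpha < 1)
  needed <- c("chrom", "start", "end", "log2")
  stopifnot(all(needed %in% names(probes)))
  with_local_seed(seed, {
    segs <- lapply(split(probes, probes$chrom)[unique(probes$chrom)],
      function(p) {
        if (is.unsorted(p$start)) stop("probes must be sorted by position")
        bounds <- segment_vector(p$log2, min_probes, alpha, permutations)
        data.frame(
          chrom = p$chrom[1],
          start = p$start[bounds$first],
          end = p$end[bounds$last],
          n_probes = bounds$last - bounds$first + 1L,
          seg_mean = vapply(
            seq_along(bounds$first),
            function(i) mean(p$log2[bounds$first[i]:bounds$last[i]]),
            numeric(1)
          ),
          stringsAsFactors = FALSE
        )
      }
    )
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
  })
}

# Recursive splitting of one numeric vector; returns parallel vectors of
# first/last probe indices per segment.
segment_vector <- function(x, min_probes, alpha, permutations) {
  n <- length(x)
  if (n < 2 * min_probes) {
    return(list(first = 1L, last = n))
  }
  sp <- best_rank_split(x, min_probes)
  pval <- split_permutation_pvalue(x, min_probes, permutations, sp$stat, alpha)
  if (pval >= alpha) {
    return(list(first = 1L, last = n))
  }
  left <- segment_vector(x[1:sp$k], min_probes, alpha, permutations)
  right <- segment_vector(x[(sp$k + 1):n], min_probes, alpha, permutations)
  list(
    first = c(left$first, right$first + sp$k),
    last = c(left$last, right$last + sp$k)
  )
}

# Max standardized rank-sum statistic over admissible boundaries k
# (left = 1..k). Under exchangeability the left rank sum W_k has mean
# k(n+1)/2 and variance k(n-k)(n+1)/12.
rank_split_stats <- function(r, min_probes) {
  n <- length(r)
  k <- seq_len(n - 1)
  w <- cumsum(r)[-n]
  z <- abs(w - k * (n + 1) / 2) / sqrt(k * (n - k) * (n + 1) / 12)
  z[k < min_probes | (n - k) < min_probes] <- -Inf
  z
}

best_rank_split <- function(x, min_probes) {
  r <- rank(x)
  z <- rank_split_stats(r, min_probes)
  k <- which.max(z)
  list(k = k, stat = z[k])
}

split_permutation_pvalue <- function(x, min_probes, permutations, observed,
                                     alpha = 1) {
  r <- rank(x)
  hits <- 0L
  # once hits guarantee p >= alpha the split is rejected either way
  cutoff <- alpha * (permutations + 1) - 1
  for (i in seq_len(permutations)) {
    zmax <- max(rank_split_stats(sample(r), min_probes))
    if (zmax >= observed) {
      hits <- hits + 1L
      if (hits > cutoff) return(alpha)
    }
  }
  (hits + 1) / (permutations + 1)
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Classify segments into gain / loss / neutral
#'
#' @param segments output of [segment_profile()].
#' @param gain_threshold,loss_threshold mean log2-ratio cutoffs
#'   (`gain_threshold > 0 > loss_threshold`); strict comparisons.
#' @return `segments` with a `state` column.
#' @export
classify_segments <- function(segments, gain_threshold = 0.2,
                              loss_threshold = -0.2) {
  stopifnot(gain_threshold > 0, loss_threshold < 0)
  state <- rep("neutral", nrow(segments))
  state[segments$seg_mean > gain_threshold] <- "gain"
  state[segments$seg_mean < loss_threshold] <- "loss"
  segments$state <- state
  segments
}

#' Arm-level copy-number events
#'
#' An arm is called gained (or lost) when segments in that state cover more
#' than `coverage_fraction` of the arm's length. When both arms of a
#' chromosome agree, a single whole-chromosome event is reported instead.
#' Chromosomes without an annotated centromere only receive
#' whole-chromosome calls.
#'
#' @param segments classified segments (with `state`).
#' @param build a [genome_build()].
#' @param coverage_fraction fraction of the arm that must be covered, in
#'   (0, 1].
#' @return data frame with `chrom`, `arm` (`"p"`, `"q"` or `"whole"`),
#'   `state`, `covered_fraction`.
#' @export
arm_events <- function(segments, build, coverage_fraction = 0.5) {
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1)
  arms <- chrom_arms(build)
  calls <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    seg <- segments[segments$chrom == a$chrom, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    arm_len <- a$end - a$start + 1
    cov <- vapply(c("gain", "loss"), function(st) {
      s <- seg[seg$state == st, , drop = FALSE]
      if (!nrow(s)) return(0)
      ov <- pmin(s$end, a$end) - pmax(s$start, a$start) + 1
      sum(pmax(ov, 0)) / arm_len
    }, numeric(1))
    st <- names(cov)[cov > coverage_fraction]
    if (!length(st)) return(NULL)
    st <- st[which.max(cov[st])]
    data.frame(
      chrom = a$chrom, arm = a$arm, state = st,
      covered_fraction = unname(cov[st]), stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) {
    return(data.frame(
      chrom = character(0), arm = character(0), state = character(0),
      covered_fraction = numeric(0)
    ))
  }
  # merge agreeing p+q calls into whole-chromosome events
  out <- lapply(split(calls, calls$chrom), function(g) {
    if (nrow(g) == 2 && all(sort(g$arm) == c("p", "q")) &&
        length(unique(g$state)) == 1) {
      data.frame(
        chrom = g$chrom[1], arm = "whole", state = g$state[1],
        covered_fraction = mean(g$covered_fraction),
        stringsAsFactors = FALSE
      )
    } else {
      g
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$arm), , drop = FALSE]
}

#' SNP depletion on copy-loss chromosomes
#'
#' In a hemizygous loss the SNPs on the lost haplotype disappear from the
#' tumor calls, so loss chromosomes show more SNPs in normal than in tumor
#' DNA. The per-chromosome measure is `100 * (N - T) / T` (percent more SNPs
#' in normal than tumor); the loss and neutral groups are compared with a
#' two-sided Welch t-test (unequal variances).
#'
#' @param normal,tumor named numeric vectors of SNP counts per chromosome
#'   (same chromosome set).
#' @param loss logical vector (or character vector of loss chromosome
#'   names): which chromosomes carry a CN loss.
#' @return list of class `depletion_result`: `per_chrom` (data frame),
#'   `loss_mean`, `loss_sd`, `neutral_mean`, `neutral_sd`, `p_value`.
#' @export
snp_depletion <- function(normal, tumor, loss) {
  chroms <- names(normal)
  if (is.null(chroms) || !identical(sort(chroms), sort(names(tumor)))) {
    stop("normal and tumor counts must be named by the same chromosomes")
  }
  tumor <- tumor[chroms]
  if (any(tumor <= 0)) stop("tumor counts must be positive")
  if (is.character(loss)) loss <- chroms %in% loss
  stopifnot(length(loss) == length(chroms))
  pct <- 100 * (normal - tumor) / tumor
  per_chrom <- data.frame(
    chrom = chroms, normal = as.numeric(normal), tumor = as.numeric(tumor),
    pct_more_in_normal = as.numeric(pct), loss = loss,
    stringsAsFactors = FALSE
  )
  grp <- function(v) c(mean = mean(v), sd = stats::sd(v))
  lossv <- pct[loss]
  neutv <- pct[!loss]
  if (sum(loss) < 2 || sum(!loss) < 2) {
    stop("p-value undefined: each group needs at least 2 chromosomes")
  }
  p <- tryCatch(
    stats::t.test(lossv, neutv, var.equal = FALSE)$p.value,
    error = function(e) NA_real_ # degenerate (constant) groups
  )
  structure(
    list(
      per_chrom = per_chrom,
      loss_mean = mean(lossv), loss_sd = stats::sd(lossv),
      neutral_mean = mean(neutv), neutral_sd = stats::sd(neutv),
      p_value = p
    ),
    class = "depletion_result"
  )
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf(
    "SNP depletion: loss chromosomes %.1f%% more SNPs in normal (sd %.1f%%), neutral %.1f%% (sd %.1f%%), Welch p = %.3g\n",
    x$loss_mean, x$loss_sd, x$neutral_mean, x$neutral_sd, x$p_value
  ))
  invisible(x)
}

#' Read / write probe tables and segment tables
#'
#' Probe TSV columns: `chrom`, `start`, `end`, `log2`. Segments are written
#' in a SEG-style TSV (`chrom`, `start`, `end`, `n_probes`, `seg_mean`,
#' `state`).
#'
#' @param path file path.
#' @export
read_probes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "log2") %in% names(df)))
  df
}

#' @param probes,segments tables to write.
#' @rdname read_probes
#' @export
write_probes <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_probes
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
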