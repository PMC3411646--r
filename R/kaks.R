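codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(codon_env$gc)) {
    gc <- Biostrings::GENETIC_CODE
    codon_env$gc <- setNames(as.character(gc), names(gc))
  }
  codon_env$gc
}

translate_codon <- function(codon) {
  gc <- genetic_code()
  aa <- gc[codon]
  ifelse(is.na(aa), "X", aa)
}

# NG86 synonymous site count of one codon: per position, the fraction of the
# three possible single-base changes that preserve the amino acid (changes to
# stop codons count as nonsynonymous).
syn_sites_codon <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, ch[p])) {
      mut <- ch
      mut[p] <- b
      mcod <- paste(mut, collapse = "")
      if (!is.na(gc[mcod]) && gc[[mcod]] == aa && gc[[mcod]] != "*") {
        s <- s + 1 / 3
      }
    }
  }
  s
}

syn_sites_table <- function() {
  if (is.null(codon_env$syn)) {
    codons <- names(genetic_code())
    codon_env$syn <- setNames(vapply(codons, syn_sites_codon, numeric(1L)),
                              codons)
  }
  codon_env$syn
}

# average synonymous/nonsynonymous differences between two codons over all
# substitution orderings; paths passing through a stop codon are excluded and
# the weights renormalized (all paths kept if every path hits a stop).
codon_path_diffs <- function(c1, c2) {
  gc <- genetic_code()
  pos <- which(strsplit(c1, "", fixed = TRUE)[[1L]] !=
               strsplit(c2, "", fixed = TRUE)[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(pos) else
    if (nd == 2L) list(pos, rev(pos)) else
      lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
             function(o) pos[o])
  step_counts <- function(order) {
    cur <- strsplit(c1, "", fixed = TRUE)[[1L]]
    tgt <- strsplit(c2, "", fixed = TRUE)[[1L]]
    syn <- 0; nonsyn <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" && nxt != c2) return(NULL)  # path through a stop
      if (gc[[prev]] == gc[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- lapply(perms, step_counts)
  ok <- !vapply(res, is.null, logical(1L))
  if (!any(ok)) {
    res <- lapply(perms, function(o) {
      cur <- strsplit(c1, "", fixed = TRUE)[[1L]]
      tgt <- strsplit(c2, "", fixed = TRUE)[[1L]]
      syn <- 0; nonsyn <- 0
      for (p in o) {
        prev <- paste(cur, collapse = "")
        cur[p] <- tgt[p]
        nxt <- paste(cur, collapse = "")
        if (gc[[prev]] == gc[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      }
      c(syn = syn, nonsyn = nonsyn)
    })
    ok <- rep(TRUE, length(res))
  }
  mat <- do.call(rbind, res[ok])
  c(syn = mean(mat[, "syn"]), nonsyn = mean(mat[, "nonsyn"]))
}

jc_correct <- function(p) {
  if (is.nan(p)) return(NaN)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks estimation
#'
#' Counts synonymous and nonsynonymous sites per codon (synonymous fraction
#' averaged over both sequences), averages multi-hit codon differences over
#' all substitution orderings (paths through stop codons excluded, weights
#' renormalized), and applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - 4p/3)`. Proportions `p >= 3/4` are flagged as
#' saturated (distance `NA`).
#'
#' @param seq_a,seq_b in-frame aligned coding sequences (equal length,
#'   multiple of 3; `-`/`N`-containing codons are dropped pairwise).
#' @param on_stop `"error"` (default) to reject internal stop codons, or
#'   `"drop"` to drop such codon pairs (useful on simulated or concatenated
#'   alignment-sliced CDS).
#' @return object of class `kaks_result`: list with `ka`, `ks`, `ka_ks`,
#'   `n_sites`, `s_sites`, `n_diff_n`, `n_diff_s`, `p_n`, `p_s`,
#'   `saturated_n`, `saturated_s`, `codons_used`.
#' @export
ng86_ka_ks <- function(seq_a, seq_b, on_stop = c("error", "drop")) {
  on_stop <- match.arg(on_stop)
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  if (nchar(seq_a) %% 3L != 0L) stop("length not divisible by 3")
  nc <- nchar(seq_a) %/% 3L
  ca <- substring(seq_a, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  cb <- substring(seq_b, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  gc <- genetic_code()
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  stop_pair <- clean & (gc[ca] == "*" | gc[cb] == "*")
  if (any(stop_pair & seq_len(nc) < nc) && on_stop == "error") {
    stop("internal stop codon in coding sequence")
  }
  keep <- clean & !stop_pair  # terminal stop codons never enter the counts
  ca <- ca[keep]; cb <- cb[keep]
  syn_tab <- syn_sites_table()
  n_codons <- length(ca)
  if (n_codons == 0L) {
    res <- list(ka = NaN, ks = NaN, ka_ks = NaN, n_sites = 0, s_sites = 0,
                n_diff_n = 0, n_diff_s = 0, p_n = NaN, p_s = NaN,
                saturated_n = FALSE, saturated_s = FALSE, codons_used = 0L)
    class(res) <- "kaks_result"
    return(res)
  }
  s_sites <- (sum(syn_tab[ca]) + sum(syn_tab[cb])) / 2
  n_sites <- 3 * n_codons - s_sites
  diff_idx <- which(ca != cb)
  sd <- 0; nd <- 0
  for (i in diff_idx) {
    d <- codon_path_diffs(ca[i], cb[i])
    sd <- sd + d[["syn"]]
    nd <- nd + d[["nonsyn"]]
  }
  p_s <- if (s_sites > 0) sd / s_sites else NaN
  p_n <- if (n_sites > 0) nd / n_sites else NaN
  ks <- jc_correct(p_s)
  ka <- jc_correct(p_n)
  res <- list(ka = ka, ks = ks,
              ka_ks = if (!is.na(ka) && !is.na(ks) && is.finite(ks) &&
                          ks > 0) ka / ks else NaN,
              n_sites = n_sites, s_sites = s_sites,
              n_diff_n = nd, n_diff_s = sd, p_n = p_n, p_s = p_s,
              saturated_n = !is.nan(p_n) && p_n >= 0.75,
              saturated_s = !is.nan(p_s) && p_s >= 0.75,
              codons_used = n_codons)
  class(res) <- "kaks_result"
  res
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> Ka = %.4g, Ks = %.4g (N = %.1f, S = %.1f sites; %d codons)%s\n",
              x$ka, x$ks, x$n_sites, x$s_sites, x$codons_used,
              if (x$saturated_s || x$saturated_n) " [saturated]" else ""))
  invisible(x)
}

#' Calibrate a substitution rate from a known divergence time
#'
#' `rate = k / (2 * t_cal)`: per-site per-year rate from a per-site distance
#' accumulated along two lineages since their split.
#'
#' @param ks per-site (synonymous) distance between the calibration pair.
#' @param t_cal_years calibration divergence time in years (> 0).
#' @param source optional description of the calibration.
#' @return list of class `rate_calibration` with `rs` (per site per year).
#' @export
calibrate_rate <- function(ks, t_cal_years, source = NULL) {
  stopifnot(t_cal_years > 0, ks >= 0)
  structure(list(rs = ks / (2 * t_cal_years),
                 source = source %||% sprintf("ks = %g over %g years",
                                              ks, t_cal_years)),
            class = "rate_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Divergence time from a synonymous distance
#'
#' `T = Ks / (2 * rs)`, reported in million years.
#'
#' @param ks per-site synonymous distance (`NA` = saturated: no date).
#' @param calibration a [calibrate_rate()] object, or a bare per-site
#'   per-year rate.
#' @return list of class `dating_result` with `t_my` (million years),
#'   `basis = "Ks"` and `saturated`.
#' @export
divergence_time <- function(ks, calibration) {
  rs <- if (inherits(calibration, "rate_calibration")) calibration$rs
        else as.numeric(calibration)
  stopifnot(rs > 0)
  if (is.na(ks)) {
    return(structure(list(t_my = NA_real_, basis = "Ks", saturated = TRUE),
                     class = "dating_result"))
  }
  structure(list(t_my = ks / (2 * rs) / 1e6, basis = "Ks", saturated = FALSE),
            class = "dating_result")
}

#' Tajima's relative rate test
#'
#' Tests equal evolutionary rates in two lineages A and B relative to an
#' outgroup: with `nA` the alignment columns where only A differs (B equals
#' the outgroup) and `nB` the converse, `chi^2 = (nA - nB)^2 / (nA + nB)`
#' with 1 df. Columns with a gap or N in any of the three rows are excluded.
#'
#' @param aln a [plastome_alignment] containing all three taxa.
#' @param a,b the two lineages compared.
#' @param outgroup the reference taxon.
#' @param columns optional integer vector restricting the test to a subset of
#'   master columns (e.g. concatenated CDS columns).
#' @return list of class `rrt_result`: `n_a`, `n_b`, `chi_square`, `p_value`,
#'   `n_sites_used`, `undefined` (TRUE when `nA + nB = 0`, reported p = 1).
#' @export
tajima_rrt <- function(aln, a, b, outgroup, columns = NULL) {
  xa <- aln_chars(aln, a)
  xb <- aln_chars(aln, b)
  xo <- aln_chars(aln, outgroup)
  keep <- xa %in% BASES & xb %in% BASES & xo %in% BASES
  if (!is.null(columns)) {
    sel <- rep(FALSE, length(keep))
    sel[columns] <- TRUE
    keep <- keep & sel
  }
  xa <- xa[keep]; xb <- xb[keep]; xo <- xo[keep]
  n_a <- sum(xa != xb & xb == xo)
  n_b <- sum(xb != xa & xa == xo)
  if (n_a + n_b == 0L) {
    res <- list(n_a = n_a, n_b = n_b, chi_square = 0, p_value = 1,
                n_sites_used = sum(keep), undefined = TRUE)
  } else {
    chi <- (n_a - n_b)^2 / (n_a + n_b)
    res <- list(n_a = n_a, n_b = n_b, chi_square = chi,
                p_value = pchisq(chi, df = 1L, lower.tail = FALSE),
                n_sites_used = sum(keep), undefined = FALSE)
  }
  class(res) <- "rrt_result"
  res
}

#' @export
print.rrt_result <- function(x, ...) {
  cat(sprintf("<rrt_result> nA = %d, nB = %d, chi^2 = %.4g, p = %.4g%s\n",
              x$n_a, x$n_b, x$chi_square, x$p_value,
              if (x$undefined) " [undefined: no informative sites]" else ""))
  invisible(x)
}
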