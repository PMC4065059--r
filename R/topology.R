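# Network diagnostics: degree and FSW distributions, power-law slope from
# a log-log linear fit, average degree, and the class composition of the
# top-ranked FSW edges.

#' Degree distribution and average degree
#'
#' `P(k)` is the fraction of nodes with degree `k`; the average degree
#' `K` equals `2|E| / |V|`.
#'
#' @param net A `pmd_network` (non-empty).
#' @return List with `degree_distribution` (data frame `k`, `p`),
#'   `average_degree`.
#' @export
degree_distribution <- function(net) {
  if (nrow(net$nodes) == 0L) stop("empty network")
  net <- update_degrees(net)
  tab <- table(net$nodes$degree)
  dist <- data.frame(k = as.integer(names(tab)),
                     p = as.numeric(tab) / nrow(net$nodes))
  list(degree_distribution = dist, average_degree = mean(net$nodes$degree))
}

#' FSW score distribution
#'
#' FSW values are binned at `bin_width` (default 0.1, i.e. scores scaled
#' by 10 to integer bins) and reported as probabilities.
#'
#' @param net A `pmd_network` with FSW on edges.
#' @param bin_width Bin width on the FSW scale.
#' @return Data frame with columns `bin` (left edge), `p`.
#' @export
fsw_distribution <- function(net, bin_width = 0.1) {
  f <- net$edges$fsw
  f <- f[!is.na(f)]
  if (length(f) == 0L) stop("no FSW scores on edges")
  b <- floor(f / bin_width + 1e-12) * bin_width
  tab <- table(b)
  data.frame(bin = as.numeric(names(tab)), p = as.numeric(tab) / length(f))
}

#' Power-law slope of a distribution
#'
#' Unweighted least-squares slope of `log P(k)` versus `log k` over bins
#' with positive probability and positive abscissa, recovering the
#' exponent gamma where `P(k)` approximates `k^gamma`.
#'
#' @param dist Data frame with columns `k` (or `bin`) and `p`.
#' @return The fitted slope (gamma).
#' @export
powerlaw_slope <- function(dist) {
  x <- if ("k" %in% names(dist)) dist$k else dist$bin
  keep <- dist$p > 0 & x > 0
  x <- x[keep]; y <- dist$p[keep]
  if (length(x) < 2L) stop("need at least 2 positive-probability bins for the fit")
  fit <- stats::lm.fit(cbind(1, log(x)), log(y))
  unname(fit$coefficients[[2]])
}

#' Topology summary of a network
#'
#' @param net A `pmd_network`.
#' @param bin_width FSW bin width (default 0.1).
#' @return List of class `pmd_topology`: `degree_distribution`,
#'   `average_degree`, `degree_slope`, `fsw_distribution` (NULL when no
#'   FSW present), `fsw_slope`.
#' @export
topology_summary <- function(net, bin_width = 0.1) {
  dd <- degree_distribution(net)
  slope <- tryCatch(powerlaw_slope(dd$degree_distribution), error = function(e) NA_real_)
  fd <- tryCatch(fsw_distribution(net, bin_width), error = function(e) NULL)
  fslope <- if (is.null(fd)) NA_real_ else
    tryCatch(powerlaw_slope(fd), error = function(e) NA_real_)
  out <- list(degree_distribution = dd$degree_distribution,
              average_degree = dd$average_degree,
              degree_slope = slope,
              fsw_distribution = fd,
              fsw_slope = fslope)
  class(out) <- "pmd_topology"
  out
}

#' Class composition of the top-ranked FSW edges
#'
#' Edges are ranked by FSW descending (ties broken by Class score rank
#' descending, then canonical pair key) and the top `ceiling(fraction *
#' |E|)` taken; per-class percentages are reported for that subset and for
#' the full edge set.
#'
#' @param net A `pmd_network` with FSW and Class scores on edges.
#' @param fraction Fraction of edges in (0, 1] to rank (default 0.10).
#' @return Data frame with columns `class`, `pct_top`, `pct_all`;
#'   percentages in each column sum to 100 over the classes present.
#' @export
score_class_composition <- function(net, fraction = 0.10) {
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]")
  }
  e <- net$edges
  if (nrow(e) == 0L) stop("network has no edges")
  ord <- order(-e$fsw, -class_rank(e$class_label), e$pair)
  top <- e[ord[seq_len(ceiling(fraction * nrow(e)))], , drop = FALSE]
  classes <- c("A", "B", "C", "D", "E", "unclassified")
  present <- classes[classes %in% unique(c(e$class_label, top$class_label))]
  pct <- function(d) 100 * vapply(present, function(cl) mean(d$class_label == cl),
                                  numeric(1))
  data.frame(class = present, pct_top = unname(pct(top)), pct_all = unname(pct(e)),
             stringsAsFactors = FALSE)
}

#' Write a topology summary TSV
#' @param summary A `pmd_topology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topology_report <- function(summary, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# average_degree\t%.6g", summary$average_degree), con)
  writeLines(sprintf("# degree_slope\t%.6g", summary$degree_slope), con)
  writeLines(sprintf("# fsw_slope\t%.6g", summary$fsw_slope), con)
  utils::write.table(summary$degree_distribution, con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(summary$fsw_distribution)) {
    writeLines("", con)
    utils::write.table(summary$fsw_distribution, con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
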