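#' Define a single-locus biallelic cross
#'
#' @param parents Character vector of two parental genotypes, each written
#'   as `"a/b"` (e.g. `c("+/-", "+/-")`).
#' @param lethal_genotypes Genotypes that do not survive (subset of the
#'   possible offspring genotypes).
#' @param observed_counts Optional named vector of observed offspring
#'   counts per genotype.
#' @return A list of class `cross_model`.
#' @export
cross_model <- function(parents = c("+/-", "+/-"),
                        lethal_genotypes = character(0),
                        observed_counts = NULL) {
  if (length(parents) != 2L) stop("exactly two parents required")
  al <- lapply(parents, function(p) strsplit(p, "/", fixed = TRUE)[[1]])
  if (any(lengths(al) != 2L)) stop("genotypes must be written as 'a/b'")
  if (!is.null(observed_counts) && any(observed_counts < 0))
    stop("observed counts must be >= 0")
  structure(list(parents = parents, alleles = al,
                 lethal_genotypes = lethal_genotypes,
                 observed_counts = observed_counts),
            class = "cross_model")
}

norm_genotype <- function(a, b) {
  # canonical order: '+' (wild-type allele) first, independent of locale
  x <- c(a, b)
  paste(x[order(x != "+", x)], collapse = "/")
}

#' Expected genotype ratios for a cross
#'
#' Punnett-square offspring fractions, before and after removing lethal
#' genotypes (post-lethality fractions are renormalized over survivors).
#' A heterozygote-by-heterozygote cross with the homozygous-null genotype
#' lethal yields surviving heterozygous and wild-type offspring at 2:1.
#'
#' @param cross A [cross_model()].
#' @return List with `pre` and `post`: named numeric vectors of genotype
#'   fractions (each summing to 1).
#' @export
expected_ratios <- function(cross) {
  stopifnot(inherits(cross, "cross_model"))
  combos <- expand.grid(a = cross$alleles[[1]], b = cross$alleles[[2]],
                        stringsAsFactors = FALSE)
  geno <- mapply(norm_genotype, combos$a, combos$b)
  pre <- table(geno) / length(geno)
  pre <- stats::setNames(as.numeric(pre), names(pre))
  bad <- setdiff(cross$lethal_genotypes, names(pre))
  if (length(bad)) stop("lethal genotype not producible by this cross: ",
                        paste(bad, collapse = ", "))
  post <- pre
  post[cross$lethal_genotypes] <- 0
  if (sum(post) == 0) stop("all offspring genotypes lethal")
  post <- post / sum(post)
  list(pre = pre, post = post)
}

#' Chi-square goodness-of-fit test of observed genotype counts
#'
#' Pearson chi-square against the expected fractions, without continuity
#' correction, with degrees of freedom equal to the number of categories
#' minus one.
#'
#' @param observed Named vector of observed counts (total must be > 0).
#' @param expected Named vector of expected fractions (must cover the
#'   observed categories; zero expected with nonzero observed is an error).
#' @return List with `statistic`, `df`, `p`.
#' @export
ratio_test <- function(observed, expected) {
  if (sum(observed) <= 0) stop("total observed count must be > 0")
  if (is.null(names(observed)) || is.null(names(expected)))
    stop("observed and expected must be named by genotype")
  e <- expected[names(observed)]
  if (any(is.na(e))) stop("expected fraction missing for: ",
                          paste(names(observed)[is.na(e)], collapse = ", "))
  if (any(e == 0 & observed > 0))
    stop("expected fraction 0 with nonzero observed count")
  keep <- e > 0
  o <- observed[keep]; e <- e[keep] / sum(e[keep])
  exp_counts <- e * sum(o)
  stat <- sum((o - exp_counts)^2 / exp_counts)
  df <- length(o) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}
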