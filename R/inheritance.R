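# Genotype tallies, germline transmission and Mendelian segregation tests.

#' Tally genotype classes among offspring
#'
#' @param genotypes Character vector of genotype-class labels (free text from
#'   upstream calling, e.g. "wild", "c.232C>T het").
#' @param founder_id Optional founder label carried into the result.
#' @return An object of class `genotype_tally`: list with `class_counts`
#'   (named integer vector), `total`, `frequencies` (percent, 1 decimal) and
#'   `founder_id`.
#' @examples
#' tally_genotypes(rep(c("c.232C>T het", "wild"), c(10, 24)))
#' @export
tally_genotypes <- function(genotypes, founder_id = NULL) {
  if (length(genotypes) == 0L) stop("no genotypes supplied", call. = FALSE)
  counts <- table(genotypes)
  counts <- counts[order(-as.integer(counts), names(counts))]
  counts <- structure(as.integer(counts), names = names(counts))
  total <- sum(counts)
  structure(list(class_counts = counts, total = total,
                 frequencies = round(100 * counts / total, 1),
                 founder_id = founder_id),
            class = "genotype_tally")
}

#' @export
print.genotype_tally <- function(x, ...) {
  hdr <- if (is.null(x$founder_id)) "" else paste0(" founder ", x$founder_id)
  cat(sprintf("<genotype_tally>%s n = %d\n", hdr, x$total))
  for (cls in names(x$class_counts)) {
    cat(sprintf("  %-20s %4d  (%.1f%%)\n", cls, x$class_counts[[cls]],
                x$frequencies[[cls]]))
  }
  invisible(x)
}

#' Chi-square test of Mendelian segregation
#'
#' Tests an observed affected count against a binomial expectation (default a
#' recessive 1/4), using the textbook one-degree-of-freedom goodness-of-fit
#' chi-square on the two classes, optionally with Yates continuity
#' correction (off by default).
#'
#' @param affected Number of affected offspring.
#' @param total Total offspring.
#' @param expected_fraction Expected affected fraction (default 0.25).
#' @param correct Apply Yates continuity correction?
#' @param alpha Significance level used for the consistency flag.
#' @return An object of class `segregation_test`: list with
#'   `observed_affected`, `total`, `observed_percent` (1 decimal),
#'   `expected_fraction`, `chi_square`, `df` (1), `p_value`, `correct`,
#'   `consistent` (TRUE when the data do not reject the expectation).
#' @examples
#' segregation_test(61, 215)   # observed 28.4%, chi-square 1.304
#' @export
segregation_test <- function(affected, total, expected_fraction = 0.25,
                             correct = FALSE, alpha = 0.05) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (affected < 0 || affected > total)
    stop("affected must lie in [0, total]", call. = FALSE)
  obs <- c(affected, total - affected)
  exp <- total * c(expected_fraction, 1 - expected_fraction)
  dev <- abs(obs - exp)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi <- sum(dev^2 / exp)
  structure(list(observed_affected = affected, total = total,
                 observed_percent = round(100 * affected / total, 1),
                 expected_fraction = expected_fraction,
                 chi_square = chi, df = 1L,
                 p_value = pchisq(chi, df = 1, lower.tail = FALSE),
                 correct = correct,
                 consistent = pchisq(chi, df = 1, lower.tail = FALSE) >= alpha),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("<segregation_test> %d/%d affected (%.1f%%) vs expected %.1f%%\n",
              x$observed_affected, x$total, x$observed_percent,
              100 * x$expected_fraction))
  cat(sprintf("  chi-square = %.3f (df 1%s), p = %.3f -> %s\n",
              x$chi_square, if (x$correct) ", Yates-corrected" else "",
              x$p_value,
              if (x$consistent) "consistent with expectation" else
                "inconsistent with expectation"))
  invisible(x)
}

#' Per-founder germline transmission summary
#'
#' A founder transmits when at least one offspring carries a non-wild
#' genotype class.
#'
#' @param f1_tallies List of `genotype_tally` objects, each tagged with a
#'   `founder_id`.
#' @param wild_label Label of the unmodified class (default "wild").
#' @return A list with `per_founder` (data.frame: `founder_id`, `n_offspring`,
#'   `n_modified`, `modified_fraction`, `transmitting`), `n_transmitting`,
#'   `n_founders`.
#' @export
transmission_rate <- function(f1_tallies, wild_label = "wild") {
  if (!length(f1_tallies)) stop("no tallies supplied", call. = FALSE)
  rows <- lapply(f1_tallies, function(t) {
    stopifnot(inherits(t, "genotype_tally"))
    if (is.null(t$founder_id)) stop("each tally needs a founder_id",
                                    call. = FALSE)
    mod <- sum(t$class_counts[setdiff(names(t$class_counts), wild_label)])
    data.frame(founder_id = t$founder_id, n_offspring = t$total,
               n_modified = mod, modified_fraction = mod / t$total,
               transmitting = mod > 0, stringsAsFactors = FALSE)
  })
  per_founder <- do.call(rbind, rows)
  rownames(per_founder) <- NULL
  list(per_founder = per_founder,
       n_transmitting = sum(per_founder$transmitting),
       n_founders = nrow(per_founder))
}

#' Read genotype calls from a TSV file
#'
#' @param file Tab-separated file with columns `sample_id`, `founder_id`,
#'   `genotype_class`.
#' @return A data.frame.
#' @export
read_genotype_calls <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "founder_id", "genotype_class")
  if (!all(need %in% names(tab)))
    stop("calls table must have columns sample_id, founder_id, genotype_class",
         call. = FALSE)
  tab
}
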