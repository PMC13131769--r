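#' Align effect alleles of a summary-statistics table to a reference panel
#'
#' Matches rows to `reference` by variant id and re-expresses every effect on
#' the reference `a1` allele: where the table's alleles are swapped relative
#' to the reference, `beta` is negated and `freq` replaced by `1 - freq`.
#' Strand-ambiguous palindromic variants (A/T or C/G) whose frequency falls
#' inside `palindrome_window` are dropped, as are variants whose allele pair
#' cannot be matched to the reference at all; both drops are logged.
#'
#' @param stats a [sumstats()] table.
#' @param reference a [variant_table()] (or data.frame with `id`, `a1`, `a2`).
#' @param palindrome_window frequency window inside which palindromic
#'   variants are considered unresolvable; default `c(0.4, 0.6)`.
#' @return A [sumstats()] table on the reference allele orientation, with
#'   attribute `n_flipped`.
#' @export
harmonize_alleles <- function(stats, reference,
                              palindrome_window = c(0.4, 0.6)) {
  ref <- as.data.frame(reference)
  j <- match(stats$snp, ref$id)
  keep_matched <- !is.na(j)
  n_unmatched_id <- sum(!keep_matched)
  s <- stats[keep_matched, , drop = FALSE]
  r <- ref[j[keep_matched], , drop = FALSE]

  same <- s$a1 == r$a1 & s$a2 == r$a2
  flip <- s$a1 == r$a2 & s$a2 == r$a1
  mismatch <- !(same | flip)

  pal <- paste0(s$a1, s$a2) %in% c("AT", "TA", "CG", "GC")
  amb <- pal & !is.na(s$freq) &
    s$freq >= palindrome_window[1] & s$freq <= palindrome_window[2]

  drop <- mismatch | amb
  if (any(drop) || n_unmatched_id > 0)
    message("harmonize_alleles: dropped ", sum(mismatch), " allele-mismatched, ",
            sum(amb), " ambiguous palindromic, ", n_unmatched_id,
            " unmatched-id row(s)")
  keep <- !drop
  s <- s[keep, , drop = FALSE]
  fl <- flip[keep]
  s$beta[fl] <- -s$beta[fl]
  s$freq[fl] <- 1 - s$freq[fl]
  tmp <- s$a1[fl]; s$a1[fl] <- s$a2[fl]; s$a2[fl] <- tmp
  rownames(s) <- NULL
  attr(s, "trait") <- attr(stats, "trait")
  attr(s, "n_flipped") <- sum(fl)
  class(s) <- c("sumstats", "data.frame")
  s
}
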