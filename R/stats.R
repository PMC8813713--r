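#' Two-by-two repeated-measures ANOVA
#'
#' Classical within-subject sums-of-squares decomposition for a complete
#' balanced 2 x 2 design with factors Tone Presentation
#' (contralateral/ipsilateral) and Hemisphere (right/left).  Each effect is
#' tested against its own subject-by-effect interaction error term with
#' degrees of freedom (1, n - 1).  Both factors have two levels, so no
#' sphericity correction is involved.  Effect size is reported as partial
#' eta squared, `SS_effect / (SS_effect + SS_error)` (classical eta squared
#' is emitted alongside).
#'
#' @param table Data.frame with columns `subject`, `presentation`
#'   (contra/ipsi), `hemisphere` (left/right) and either a `value` column, a
#'   column named as `measure`, or long columns `measure`/`value`.
#' @param measure Which measure to analyse (column name or level of a long
#'   `measure` column); optional when `table` has a `value` column.
#' @return An `AnovaResult` data.frame with one row per effect
#'   (presentation, hemisphere, interaction) and columns F, df1, df2, p,
#'   eta_p2, eta2.
#' @export
rmAnova2x2 <- function(table, measure = NULL) {
  need <- c("subject", "presentation", "hemisphere")
  if (!all(need %in% names(table)))
    stop("'table' must have columns subject, presentation, hemisphere",
         call. = FALSE)
  if ("measure" %in% names(table) && "value" %in% names(table)) {
    if (is.null(measure)) stop("long table: 'measure' must be given", call. = FALSE)
    table <- table[table$measure == measure, , drop = FALSE]
    y <- table$value
  } else if (!is.null(measure)) {
    if (!measure %in% names(table))
      stop("no column '", measure, "' in table", call. = FALSE)
    y <- table[[measure]]
  } else if ("value" %in% names(table)) {
    y <- table$value
  } else stop("no measure column found", call. = FALSE)

  s <- factor(table$subject)
  a <- factor(table$presentation)
  b <- factor(table$hemisphere)
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop("both factors must have exactly 2 levels", call. = FALSE)
  n <- nlevels(s)
  if (n < 2) stop("at least 2 subjects are required", call. = FALSE)
  # completeness: every subject must have all 4 cells exactly once
  tab <- table(s, a, b)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    msg <- apply(bad, 1, function(r)
      sprintf("(%s, %s/%s)", levels(s)[r[1]], levels(a)[r[2]], levels(b)[r[3]]))
    stop("design is not complete/balanced; offending cells: ",
         paste(msg, collapse = ", "), call. = FALSE)
  }

  M <- mean(y)
  Ms <- tapply(y, s, mean)
  Ma <- tapply(y, a, mean)
  Mb <- tapply(y, b, mean)
  Mab <- tapply(y, list(a, b), mean)
  Msa <- tapply(y, list(s, a), mean)
  Msb <- tapply(y, list(s, b), mean)

  ss_a <- 2 * n * sum((Ma - M)^2)
  ss_b <- 2 * n * sum((Mb - M)^2)
  ss_ab <- n * sum((Mab - outer(Ma - M, Mb - M, "+") - M)^2)
  ss_as <- 2 * sum((Msa - outer(Ms - M, Ma - M, "+") - M)^2)
  ss_bs <- 2 * sum((Msb - outer(Ms - M, Mb - M, "+") - M)^2)
  ycell <- tapply(y, list(s, a, b), mean)
  resid <- ycell
  for (i in seq_len(n)) for (j in 1:2) for (k in 1:2)
    resid[i, j, k] <- ycell[i, j, k] - Msa[i, j] - Msb[i, k] - Mab[j, k] +
      Ms[i] + Ma[j] + Mb[k] - M
  ss_abs <- sum(resid^2)
  ss_tot <- sum((y - M)^2)

  eff <- function(ss, sserr) {
    Fv <- if (sserr <= 0) {
      if (ss <= 1e-12 * max(ss_tot, 1)) 0 else Inf
    } else (ss / 1) / (sserr / (n - 1))
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    c(F = Fv, df1 = 1, df2 = n - 1, p = p,
      eta_p2 = if (ss + sserr > 0) ss / (ss + sserr) else 0,
      eta2 = if (ss_tot > 0) ss / ss_tot else 0)
  }
  out <- rbind(presentation = eff(ss_a, ss_as),
               hemisphere = eff(ss_b, ss_bs),
               interaction = eff(ss_ab, ss_abs))
  out <- data.frame(effect = rownames(out), out, row.names = NULL)
  class(out) <- c("AnovaResult", "data.frame")
  out
}
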