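# Single-cell sequencing error model: conditional probabilities of the
# observed state given the true genotype, with false-positive rate alpha and
# false-negative (allelic dropout) rate beta, plus handling of missing ("-")
# and ambiguous ("?") observations.
#
# Observed matrices are integer matrices with entries 0/1/2, NA for missing,
# and -1L for ambiguous.

MO_AMBIGUOUS <- -1L

#' Conditional error probability matrix
#'
#' Rows index the true genotype, columns the observed state. For binary data
#' the rows are `(1-a, a)` and `(b, 1-b)`. For ternary data a true
#' heterozygote can drop either allele (each with probability `b/2`), a true
#' reference site can be miscalled heterozygous (`a`) or, rarely, homozygous
#' non-reference (`a b / 2`), and a true homozygous non-reference genotype is
#' always observed as 2.
#'
#' @param alpha false-positive probability in `[0, 1]`.
#' @param beta false-negative probability in `[0, 1]`.
#' @param mode `"binary"` or `"ternary"`.
#' @return a stochastic matrix (2x2 or 3x3), rows = true genotype.
#' @examples
#' error_matrix(0.1, 0.2, "ternary")[1, ]  # 0.89 0.10 0.01
#' @export
error_matrix <- function(alpha, beta, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  if (mode == "binary") {
    return(matrix(c(1 - alpha, alpha, beta, 1 - beta), nrow = 2, byrow = TRUE,
                  dimnames = list(true = c("0", "1"), obs = c("0", "1"))))
  }
  p00 <- 1 - alpha - alpha * beta / 2
  if (p00 < 0)
    stop("invalid ternary error rates: alpha + alpha*beta/2 > 1", call. = FALSE)
  matrix(c(p00, alpha, alpha * beta / 2,
           beta / 2, 1 - beta, beta / 2,
           0, 0, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(true = c("0", "1", "2"), obs = c("0", "1", "2")))
}

n_states <- function(mode) if (mode == "binary") 2L else 3L

# Per-cell log P(observation | true state) for one site: returns a
# (#cells) x (#states) matrix. Ambiguous entries are weighted sums over
# possible observed states (Eq.-16-style); default weights are uniform.
cell_obs_loglik <- function(s_row, alpha, beta, mode, weights = NULL) {
  ns <- n_states(mode)
  J <- length(s_row)
  alpha <- rep_len(alpha, J)
  beta <- rep_len(beta, J)
  out <- matrix(NA_real_, J, ns)
  for (j in seq_len(J)) {
    N <- error_matrix(alpha[j], beta[j], mode)
    s <- s_row[j]
    if (is.na(s)) next  # missing cells are excluded upstream
    if (s == MO_AMBIGUOUS) {
      w <- if (!is.null(weights) && !is.null(weights[[j]])) weights[[j]]
           else rep(1 / ns, ns)
      stopifnot(length(w) == ns, all(w >= 0))
      w <- w / sum(w)
      out[j, ] <- log(as.vector(N %*% w))
    } else {
      if (s < 0 || s >= ns)
        stop("observed state ", s, " invalid for ", mode, " data", call. = FALSE)
      out[j, ] <- log(N[, s + 1L])
    }
  }
  out
}

#' Log-likelihood of one site's observations given true genotypes
#'
#' Computes `log prod_j sum_k w_jk P(S_jk | G_j)` over the supplied cells.
#' Point observations contribute `log N[G_j, S_j]`; ambiguous observations
#' (`-1L`) are weighted over possible states (uniform by default); `NA`
#' (missing) cells must have been excluded upstream via [project_subtree()]
#' and are an error here.
#'
#' @param s_row integer vector of observed states for the kept cells.
#' @param g integer vector of true genotypes, same length.
#' @param alpha,beta scalar or per-cell error probabilities.
#' @param mode `"binary"` or `"ternary"`.
#' @param weights optional list (per cell) of ambiguity weight vectors.
#' @return scalar log-likelihood; `-Inf` with attribute `zero = TRUE` when an
#'   observation is impossible under the error model.
#' @export
site_likelihood <- function(s_row, g, alpha, beta,
                            mode = c("binary", "ternary"), weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(s_row) == length(g))
  if (anyNA(s_row))
    stop("missing observations must be excluded before computing the ",
         "likelihood (see project_subtree)", call. = FALSE)
  L <- cell_obs_loglik(s_row, alpha, beta, mode, weights)
  ll <- sum(L[cbind(seq_along(g), g + 1L)])
  if (!is.finite(ll)) {
    ll <- -Inf
    attr(ll, "zero") <- TRUE
  }
  ll
}

#' Read / write a mutation matrix
#'
#' Tab-separated (comma autodetected) matrix with a header row of cell
#' labels and a first column of site labels. Entries are `0`, `1`, `2`
#' (ternary only), `-` for missing and `?` for ambiguous. The strict parser
#' reports the line and column of any offending entry.
#'
#' @param file path to the matrix file.
#' @param mode `"binary"` or `"ternary"`; binary data admit no `2`.
#' @return an integer matrix (sites x cells) with `NA` for missing and `-1L`
#'   for ambiguous entries, `dimnames` from the file, and attribute `mode`.
#' @export
read_mutation_matrix <- function(file, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  first <- readLines(file, n = 1L)
  sep <- if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
  raw <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1L,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  m <- as.matrix(raw)
  ok <- c("0", "1", "-", "?", if (mode == "ternary") "2")
  bad <- which(matrix(!(m %in% ok), nrow(m)), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stop("invalid entry '", m[b[1], b[2]], "' at site ", rownames(m)[b[1]],
         " (row ", b[1], "), cell ", colnames(m)[b[2]], " (column ", b[2],
         ") for ", mode, " data", call. = FALSE)
  }
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == "0"] <- 0L
  out[m == "1"] <- 1L
  if (mode == "ternary") out[m == "2"] <- 2L
  out[m == "?"] <- MO_AMBIGUOUS
  attr(out, "mode") <- mode
  out
}

#' @rdname read_mutation_matrix
#' @param x integer matrix as returned by [read_mutation_matrix()].
#' @export
write_mutation_matrix <- function(x, file) {
  m <- matrix("-", nrow(x), ncol(x), dimnames = dimnames(x))
  m[!is.na(x) & x >= 0] <- as.character(x[!is.na(x) & x >= 0])
  m[!is.na(x) & x == MO_AMBIGUOUS] <- "?"
  df <- data.frame(site = rownames(x) %||% paste0("s", seq_len(nrow(x))), m,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
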