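# Small numerical helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded package functions never disturb the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax
#' @param x Numeric matrix.
#' @return Matrix of the same shape with rows summing to 1.
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

# Glorot-uniform initialisation for a dense layer.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Adam optimiser state
#'
#' Creates the moment accumulators for a flat named list of parameter
#' arrays. `adam_step()` applies one update in place (functionally) and
#' returns the updated parameters and state.
#'
#' @param params Named list of numeric arrays.
#' @param lr Learning rate.
#' @param beta1,beta2 Exponential decay rates for the moment estimates.
#' @param eps Numerical stabiliser.
#' @return An optimiser state list.
#' @keywords internal
adam_init <- function(params, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps)
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table to TSV with exact double round-tripping
#'
#' Doubles are written with 17 significant digits so that reading the file
#' back yields bit-identical values.
#' @param df Data frame.
#' @param path Output path.
#' @param row_names Prepend row names as a first column.
#' @return Invisibly, `path`.
#' @export
write_tsv_exact <- function(df, path, row_names = FALSE) {
  fmt <- function(col) {
    if (is.double(col)) {
      out <- formatC(col, digits = 17, format = "g")
      out[is.na(col)] <- "NA"
      trimws(out)
    } else {
      as.character(col)
    }
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (row_names) out <- cbind(row = rownames(df), out)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv_utf8 <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8", ...)
}
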