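## Internal helpers.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream.  All stochastic operations in the package route through this so
## that results are reproducible given their `seed` argument.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a reproducible child seed, kept inside 32-bit integer range.
childSeed <- function(seed, offset) {
    as.integer((as.double(seed) * 7919 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Mean that returns NA (not NaN) on empty input.
meanOrNA <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else mean(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to compare recovered promoter clusters with planted architecture
#' classes.  1 = identical partitions (up to label permutation), 0 =
#' agreement expected by chance.
#'
#' @param a,b label vectors of equal length; pairs with NA in either are
#'   dropped.
#' @return A single number in [-1, 1].
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 2L) return(NA_real_)
    tab <- table(a, b)
    choose2 <- function(x) x * (x - 1) / 2
    sumij <- sum(choose2(tab))
    ai <- sum(choose2(rowSums(tab)))
    bj <- sum(choose2(colSums(tab)))
    n2 <- choose2(length(a))
    expected <- ai * bj / n2
    maxidx <- (ai + bj) / 2
    if (maxidx == expected) return(1)
    (sumij - expected) / (maxidx - expected)
}
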