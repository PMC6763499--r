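# Shared internal helpers.

# Average-tie ranks along the rows of a matrix (signatures x cells).
rank_rows <- function(x) {
  if (is.null(dim(x))) {
    return(rank(x, ties.method = "average"))
  }
  t(apply(x, 1L, rank, ties.method = "average"))
}

# Benjamini-Hochberg adjustment; thin wrapper so every result table goes
# through the same call.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Case-insensitive gene matching: returns integer indices into `universe`
# for the elements of `genes` that are present, dropping the rest.
match_genes <- function(genes, universe) {
  idx <- match(toupper(genes), toupper(universe))
  idx[!is.na(idx)]
}

# Population (1/n) variance.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

check_expression <- function(expr, arg = "expr") {
  if (!is.matrix(expr) && !methods::is(expr, "Matrix")) {
    abort(sprintf("`%s` must be a genes x cells matrix.", arg))
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort(sprintf("`%s` must carry gene rownames and cell colnames.", arg))
  }
  if (anyDuplicated(colnames(expr))) {
    abort("Duplicate cell identifiers in expression matrix.")
  }
  invisible(expr)
}

# Local RNG scope: runs `expr` under `seed` and restores the caller's RNG
# state, so one pipeline seed governs every stochastic step without
# clobbering the session.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
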