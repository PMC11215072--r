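#' @import methods
#' @importFrom stats optim prcomp rnorm runif sd var cor quantile setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit hash of a string combined with a global seed, used to
# fan one pipeline seed out into independent per-stage seeds.
#' Derive a per-stage random seed from a global seed
#'
#' Stable integer hash combining a global seed with a stage name, so that
#' every pipeline stage is independently reproducible from one seed.
#'
#' @param globalSeed integer global seed.
#' @param stageName character scalar naming the stage.
#' @return an integer in `[0, 2^31)`.
#' @export
stageSeed <- function(globalSeed, stageName) {
  stopifnot(is.numeric(globalSeed), length(globalSeed) == 1L,
            is.character(stageName), length(stageName) == 1L)
  m <- 2147483647           # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(globalSeed) %% m
  for (code in utf8ToInt(stageName)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# ---- flatten / unflatten nested parameter lists -----------------------------
# Parameter sets are nested named lists whose leaves are numeric arrays.
# Flattening to one vector makes the Adam update a single vectorised step.

flattenParams <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, flattenParams), use.names = FALSE))
  as.numeric(p)
}

unflattenParams <- function(vec, skeleton, pos = 1L) {
  if (is.list(skeleton)) {
    out <- vector("list", length(skeleton))
    names(out) <- names(skeleton)
    for (i in seq_along(skeleton)) {
      r <- unflattenParams(vec, skeleton[[i]], pos)
      out[[i]] <- r$value
      pos <- r$pos
    }
    return(list(value = out, pos = pos))
  }
  n <- length(skeleton)
  leaf <- vec[pos:(pos + n - 1L)]
  dim(leaf) <- dim(skeleton)
  list(value = leaf, pos = pos + n)
}

# Convenience wrapper returning just the structure.
relistParams <- function(vec, skeleton) {
  unflattenParams(vec, skeleton)$value
}

# md5 of an R object via its canonical JSON, for stage manifests.
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
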