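# Minimal reverse-mode tape over dense arrays. Nodes are environments holding
# a value, an accumulated gradient and a backward closure; the tape records
# creation order, and ad_backward() replays it in reverse. Heavy kernels
# (convolutions, pooling, resampling) live in src/kernels.cpp; cheap
# elementwise ops stay vectorised in R.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- n
  n
}

ad_param <- function(tape, value) ad_node(tape, value)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# Backpropagate from a scalar node. After the call every parameter node
# reachable from `root` carries its gradient in $grad.
ad_backward <- function(tape, root) {
  root$grad <- 1
  for (i in seq(tape$n, 1L)) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      if (!is.null(gs[[j]])) ad_accum(n$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}
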