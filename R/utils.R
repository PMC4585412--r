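# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's RNG afterwards, so generators are deterministic without
# clobbering the session RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
mshift <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# 8-connected component labelling. EBImage::bwlabel() is 4-connected;
# labels touching diagonally are merged afterwards so thin diagonal leaf
# tips do not fragment.
label8 <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  pairs <- NULL
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nrow(lab) - 1L), , drop = FALSE]
    if (d[2] == 1L) {
      a <- a[, seq_len(ncol(lab) - 1L), drop = FALSE]
      b <- lab[-1L, -1L, drop = FALSE]
    } else {
      a <- a[, -1L, drop = FALSE]
      b <- lab[-1L, seq_len(ncol(lab) - 1L), drop = FALSE]
    }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  nmax <- max(lab)
  if (!is.null(pairs)) {
    g <- igraph::make_graph(t(unique(pairs)), n = nmax, directed = FALSE)
    comp <- igraph::components(g)$membership
    lab[lab > 0L] <- comp[lab[lab > 0L]]
  }
  # renumber components by order of first appearance (top row, then left col)
  ids <- unique(lab[lab > 0L])
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Euclidean distance transform (distance of foreground pixels to the
# nearest background pixel), as a plain matrix.
distanceMap <- function(mask) {
  as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))))
}
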