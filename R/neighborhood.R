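#' Random-walk configuration
#'
#' Parameters of the second-order biased random walks used to sample a
#' protein's network neighborhood. `p` is the return parameter (small `p`
#' keeps the walk near the source), `q` the in-out parameter (small `q`
#' drives the walk outward, depth-first-like); with `p = q = 1` the walk is
#' an unbiased first-order random walk. The defaults (`p = q = 0.25`,
#' walk length 100, 18 walks per source) bias the walks toward the community
#' around the source protein.
#'
#' @param p return parameter, > 0
#' @param q in-out parameter, > 0
#' @param l walk length (number of nodes per walk), >= 2
#' @param r number of walks per source node, >= 2
#' @param seed integer seed; each source derives its own stream from it so
#'   neighborhoods do not depend on processing order
#' @param min_walks a node must appear in at least this many distinct walks
#'   to enter the neighborhood (default 2, i.e. "more than one walk")
#' @return an object of class `walk_config`
#' @export
walk_config <- function(p = 0.25, q = 0.25, l = 100L, r = 18L, seed = 1L,
                        min_walks = 2L) {
  if (!is.numeric(p) || p <= 0) stop("`p` must be > 0")
  if (!is.numeric(q) || q <= 0) stop("`q` must be > 0")
  l <- as.integer(l); r <- as.integer(r); min_walks <- as.integer(min_walks)
  if (l < 2L) stop("walk length `l` must be >= 2")
  if (r < 2L) stop("number of walks `r` must be >= 2")
  if (min_walks < 1L) stop("`min_walks` must be >= 1")
  structure(list(p = p, q = q, l = l, r = r, seed = as.integer(seed),
                 min_walks = min_walks),
            class = "walk_config")
}

#' Second-order walk bias
#'
#' The bias applied to a candidate next node `x` given the previously visited
#' node `t`: `1/p` when `x` is `t` itself (`d_tx = 0`), 1 when `x` is
#' adjacent to `t` (`d_tx = 1`) and `1/q` when `x` is two steps from `t`
#' (`d_tx = 2`). Within one walk step these are the only possible distances.
#'
#' @param d_tx integer (vector) of shortest-path distances in `{0, 1, 2}`
#' @param cfg a [walk_config()]
#' @return numeric vector of biases
#' @export
transition_bias <- function(d_tx, cfg) {
  if (!all(d_tx %in% c(0L, 1L, 2L))) {
    stop("`d_tx` must be 0, 1 or 2")
  }
  out <- rep(1, length(d_tx))
  out[d_tx == 0L] <- 1 / cfg$p
  out[d_tx == 2L] <- 1 / cfg$q
  out
}

#' Transition probabilities of the biased walk
#'
#' Probability distribution over the neighbors of the current node `v`, given
#' the previously visited node `t`: proportional to `alpha_pq(t, x) * w_vx`,
#' normalized to sum to one. For the first step of a walk (no previous node)
#' pass `t = NA`; the distribution is then uniform over the neighbors of `v`.
#'
#' @param t previous node id, or `NA`/`NULL` for the first step
#' @param v current node id
#' @param net a `ppi_network`
#' @param cfg a [walk_config()]
#' @return named numeric vector of probabilities over neighbors of `v`
#' @export
transition_probs <- function(t, v, net, cfg) {
  stopifnot(inherits(net, "ppi_network"))
  iv <- match(v, net$nodes)
  if (is.na(iv)) stop(sprintf("node '%s' is not in the network", v))
  nb <- net$adj_idx[[iv]]
  if (!length(nb)) stop(sprintf("node '%s' is isolated: walk dead end", v))
  w <- net$adj_w[[iv]]
  if (is.null(t) || is.na(t)) {
    pr <- rep(1 / length(nb), length(nb))   # first step: no bias available
    names(pr) <- net$nodes[nb]
    return(pr)
  }
  it <- match(t, net$nodes)
  if (is.na(it) || !(it %in% nb)) {
    stop(sprintf("previous node '%s' is not a neighbor of '%s'", t, v))
  }
  d <- integer(length(nb)) + 2L
  d[nb %in% net$adj_idx[[it]]] <- 1L
  d[nb == it] <- 0L
  pr <- transition_bias(d, cfg) * w
  pr <- pr / sum(pr)
  names(pr) <- net$nodes[nb]
  pr
}

# Deterministic per-source seed in [0, 2^31 - 2]; depends on the global seed
# and a hash of the source id so that neighborhoods are independent of the
# order in which sources are processed.
seed_for_source <- function(seed, source) {
  h <- sum(utf8ToInt(source) * seq_along(utf8ToInt(source))) %% 1000003
  as.integer((as.double(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

#' Sample biased random walks from a source node
#'
#' Generates `cfg$r` walks of `cfg$l` nodes each, starting at `source`. The
#' first step is uniform over the source's neighbors; subsequent steps follow
#' [transition_probs()]. Walks are reproducible given `cfg$seed` and do not
#' depend on which other sources have been walked. An isolated source yields
#' `r` single-node walks and a warning.
#'
#' @param source source node id (must be in the network)
#' @param net a `ppi_network`
#' @param cfg a [walk_config()]
#' @return an object of class `walk_set`: list with `source` and `walks`
#'   (list of character vectors)
#' @export
sample_walks <- function(source, net, cfg) {
  stopifnot(inherits(net, "ppi_network"), inherits(cfg, "walk_config"))
  is0 <- match(source, net$nodes)
  if (is.na(is0)) stop(sprintf("source '%s' is not in the network", source))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed_for_source(cfg$seed, source))

  adj <- net$adj_idx
  adjw <- net$adj_w
  if (!length(adj[[is0]])) {
    warning(sprintf("source '%s' is isolated; returning single-node walks", source))
    walks <- replicate(cfg$r, source, simplify = FALSE)
    return(structure(list(source = source, walks = walks, config = cfg),
                     class = "walk_set"))
  }

  # memoized second-order transition distributions keyed by (t, v)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  nn <- length(net$nodes)
  step_dist <- function(it, iv) {
    key <- as.character(it * (nn + 1L) + iv)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    nb <- adj[[iv]]
    d <- integer(length(nb)) + 2L
    d[nb %in% adj[[it]]] <- 1L
    d[nb == it] <- 0L
    a <- rep(1, length(nb))
    a[d == 0L] <- 1 / cfg$p
    a[d == 2L] <- 1 / cfg$q
    pr <- a * adjw[[iv]]
    res <- list(nb = nb, pr = pr / sum(pr))
    memo[[key]] <- res
    res
  }

  walks <- vector("list", cfg$r)
  for (k in seq_len(cfg$r)) {
    w <- integer(cfg$l)
    w[1L] <- is0
    nb0 <- adj[[is0]]
    w[2L] <- if (length(nb0) == 1L) nb0 else nb0[sample.int(length(nb0), 1L)]
    i <- 2L
    while (i < cfg$l) {
      cur <- w[i]
      nb <- adj[[cur]]
      if (!length(nb)) break          # dead end guard; truncated walk kept
      sd <- step_dist(w[i - 1L], cur)
      nxt <- if (length(sd$nb) == 1L) sd$nb else sd$nb[sample.int(length(sd$nb), 1L, prob = sd$pr)]
      i <- i + 1L
      w[i] <- nxt
    }
    walks[[k]] <- net$nodes[w[seq_len(i)]]
  }
  structure(list(source = source, walks = walks, config = cfg),
            class = "walk_set")
}

#' @export
print.walk_set <- function(x, ...) {
  cat(sprintf("<walk_set> source %s: %d walks, lengths %s\n", x$source,
              length(x$walks),
              paste(range(lengths(x$walks)), collapse = "-")))
  invisible(x)
}

#' Derive a neighborhood from a walk set
#'
#' A node (other than the source) belongs to the source's neighborhood when
#' it appears in at least `min_walks` *distinct* walks of the walk set;
#' repeated visits within a single walk do not count. The measured
#' neighborhood is the intersection with the measured node set `U`.
#'
#' @param ws a `walk_set` from [sample_walks()]
#' @param U character vector of measured base-node ids (defaults to empty)
#' @param min_walks minimum number of distinct walks (default taken from the
#'   walk configuration stored in `ws`, itself defaulting to 2)
#' @return an object of class `neighborhood`: list with `source`, `members`
#'   (sorted character vector `N_u`) and `measured_members` (`M_i`)
#' @export
derive_neighborhood <- function(ws, U = character(), min_walks = NULL) {
  stopifnot(inherits(ws, "walk_set"))
  if (length(ws$walks) < 2L) stop("need at least 2 walks to derive a neighborhood")
  if (is.null(min_walks)) {
    min_walks <- if (!is.null(ws$config)) ws$config$min_walks else 2L
  }
  visits <- table(unlist(lapply(ws$walks, unique), use.names = FALSE))
  members <- sort(setdiff(names(visits)[visits >= min_walks], ws$source))
  structure(
    list(source = ws$source, members = members,
         measured_members = intersect(members, U)),
    class = "neighborhood"
  )
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood> %s: %d members (%d measured)\n",
              x$source, length(x$members), length(x$measured_members)))
  invisible(x)
}

#' Sample neighborhoods for a set of source proteins
#'
#' Convenience wrapper: runs [sample_walks()] and [derive_neighborhood()] for
#' every source, returning a named list of neighborhoods. Sources with empty
#' measured neighborhoods are reported via `message()`.
#'
#' @param net a `ppi_network`
#' @param sources character vector of source node ids (typically the measured
#'   base nodes `U`)
#' @param cfg a [walk_config()]
#' @param U measured node set used for `measured_members`; defaults to
#'   `sources`
#' @return named list of `neighborhood` objects
#' @export
sample_neighborhoods <- function(net, sources, cfg = walk_config(), U = sources) {
  out <- lapply(sources, function(s) {
    derive_neighborhood(sample_walks(s, net, cfg), U = setdiff(U, s))
  })
  names(out) <- sources
  empty <- sources[vapply(out, function(nb) length(nb$measured_members) == 0L, logical(1))]
  if (length(empty)) {
    message(sprintf("%d source(s) have no measured neighbors: %s",
                    length(empty), paste(utils::head(empty, 5L), collapse = ", ")))
  }
  out
}

#' Write neighborhoods to a TSV file
#'
#' One row per source: `source<TAB>comma-joined members`.
#'
#' @param neighborhoods named list of `neighborhood` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_neighborhoods <- function(neighborhoods, path) {
  df <- data.frame(
    source = vapply(neighborhoods, `[[`, character(1), "source"),
    members = vapply(neighborhoods, function(nb) paste(nb$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read neighborhoods from a TSV file written by [write_neighborhoods()]
#'
#' @param path input path
#' @param U measured node set used to recompute `measured_members`
#' @return named list of `neighborhood` objects
#' @export
read_neighborhoods <- function(path, U = character()) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i) {
    members <- if (nzchar(df$members[i])) strsplit(df$members[i], ",", fixed = TRUE)[[1L]] else character()
    structure(list(source = df$source[i], members = sort(members),
                   measured_members = intersect(sort(members), setdiff(U, df$source[i]))),
              class = "neighborhood")
  })
  names(out) <- df$source
  out
}
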