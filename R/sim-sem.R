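#' Configuration for a mixed-type structural equation model
#'
#' Ground-truth fixture for constraint-based causal discovery: a DAG with
#' linear-Gaussian continuous variables and logistic-link binary children.
#'
#' @param variables data.frame with columns `name` and `type`
#'   (`"continuous"` or `"binary"`).
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param noise_sd Residual standard deviation of continuous variables.
#' @param intercept Intercept of logistic links for binary children.
#' @param n Number of rows to simulate.
#' @return A `sem_config` list; errors if the edge set has a cycle.
#' @export
sem_config <- function(variables, edges, noise_sd = 1, intercept = 0,
                       n = 1000L) {
  stopifnot(all(c("name", "type") %in% names(variables)),
            all(c("from", "to", "weight") %in% names(edges)) ||
              nrow(edges) == 0L)
  if (anyDuplicated(variables$name)) stop("duplicate variable names",
                                          call. = FALSE)
  if (nrow(edges) > 0L &&
      !all(c(edges$from, edges$to) %in% variables$name))
    stop("edge endpoints must be declared variables", call. = FALSE)
  cfg <- structure(list(variables = variables, edges = edges,
                        noise_sd = noise_sd, intercept = intercept,
                        n = as.integer(n)),
                   class = "sem_config")
  .topo_order(cfg)  # errors on cycles
  cfg
}

# Kahn topological sort; errors if a cycle exists.
.topo_order <- function(cfg) {
  vars <- cfg$variables$name
  indeg <- setNames(integer(length(vars)), vars)
  if (nrow(cfg$edges)) {
    tab <- table(cfg$edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  queue <- vars[indeg == 0L]
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    if (nrow(cfg$edges)) {
      ch <- cfg$edges$to[cfg$edges$from == v]
      for (c_ in ch) {
        indeg2[c_] <- indeg2[c_] - 1L
        if (indeg2[c_] == 0L) queue <- c(queue, c_)
      }
    }
  }
  if (length(order) != length(vars))
    stop("cycle detected in SEM edge set", call. = FALSE)
  order
}

#' Simulate a mixed-type dataset from a SEM
#'
#' Variables are simulated in topological order: continuous children are
#' linear in their parents with Gaussian noise; binary children follow a
#' logistic link.
#'
#' @param cfg A [sem_config()].
#' @param seed Integer seed.
#' @return List with `data` (data.frame), `types` (named character) and
#'   `truth` (true adjacency matrix `adj[i, j] = 1` for edge i -> j, and
#'   the edge list).
#' @export
generate_sem <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sem_config"))
  set.seed(seed)
  ord <- .topo_order(cfg)
  n <- cfg$n
  dat <- as.data.frame(matrix(NA_real_, n, length(ord)))
  names(dat) <- ord
  types <- setNames(cfg$variables$type, cfg$variables$name)
  for (v in ord) {
    pa <- cfg$edges[cfg$edges$to == v, , drop = FALSE]
    lin <- rep(0, n)
    if (nrow(pa)) {
      for (k in seq_len(nrow(pa)))
        lin <- lin + pa$weight[k] * dat[[pa$from[k]]]
    }
    if (types[[v]] == "continuous") {
      dat[[v]] <- lin + stats::rnorm(n, 0, cfg$noise_sd)
    } else {
      p <- stats::plogis(cfg$intercept + lin)
      dat[[v]] <- stats::rbinom(n, 1L, p)
    }
  }
  dat <- dat[, cfg$variables$name, drop = FALSE]
  vars <- cfg$variables$name
  adj <- matrix(0L, length(vars), length(vars), dimnames = list(vars, vars))
  if (nrow(cfg$edges))
    adj[cbind(cfg$edges$from, cfg$edges$to)] <- 1L
  list(data = dat, types = types[vars],
       truth = list(adjacency = adj, edges = cfg$edges))
}

#' Random DAG SEM configuration
#'
#' Convenience constructor for recovery benchmarks: a random DAG on `p`
#' continuous variables (upper-triangular under a random order), each
#' possible edge present with probability `edge_prob` and weight drawn
#' uniformly from `weight_range` with random sign.
#'
#' @param p Number of variables.
#' @param edge_prob Edge probability.
#' @param weight_range Absolute weight range, default `c(0.5, 1)`.
#' @param n Sample size.
#' @param seed Integer seed for the structure.
#' @return A [sem_config()].
#' @export
random_sem_config <- function(p, edge_prob = 0.35,
                              weight_range = c(0.5, 1), n = 2000L,
                              seed = 1L) {
  set.seed(seed)
  vars <- sprintf("V%d", seq_len(p))
  perm <- sample(vars)
  ed <- list()
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    if (stats::runif(1) < edge_prob) {
      w <- stats::runif(1, weight_range[1], weight_range[2]) *
        sample(c(-1, 1), 1)
      ed[[length(ed) + 1L]] <- data.frame(from = perm[i], to = perm[j],
                                          weight = w)
    }
  }
  edges <- if (length(ed)) do.call(rbind, ed) else
    data.frame(from = character(0), to = character(0),
               weight = numeric(0))
  sem_config(data.frame(name = vars, type = "continuous",
                        stringsAsFactors = FALSE),
             edges, n = n)
}
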