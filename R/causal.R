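#' Mixed-type dataset for causal discovery
#'
#' Continuous variables are z-standardised (callers log2-transform
#' upstream where appropriate); categorical variables are kept as factors
#' and dummy-encoded internally. Categorical variables may have more than
#' two levels as conditioning variables, but conditional-independence
#' tests between two multi-level variables are not supported.
#'
#' @param data Data.frame.
#' @param types Named character vector (`"continuous"` / `"categorical"`
#'   / `"binary"`) for every column; binary is treated as categorical.
#' @param standardize Standardise continuous columns (default TRUE).
#' @return A `mixed_dataset`.
#' @export
mixed_dataset <- function(data, types, standardize = TRUE) {
  stopifnot(is.data.frame(data), all(names(data) %in% names(types) |
                                       names(types) %in% names(data)))
  types <- types[names(data)]
  types[types == "binary"] <- "categorical"
  if (!all(types %in% c("continuous", "categorical")))
    stop("types must be continuous/categorical/binary", call. = FALSE)
  for (v in names(data)) {
    if (types[[v]] == "continuous") {
      x <- as.numeric(data[[v]])
      if (standardize) {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0)
          stop("constant continuous variable: ", v, call. = FALSE)
        x <- (x - mean(x)) / s
      }
      data[[v]] <- x
    } else {
      f <- factor(data[[v]])
      if (nlevels(f) < 2L)
        stop("categorical variable with < 2 levels: ", v, call. = FALSE)
      data[[v]] <- f
    }
  }
  structure(list(data = data, types = types, n = nrow(data)),
            class = "mixed_dataset")
}

# numeric encoding: continuous -> 1 column; categorical L levels -> L-1
# dummies. Returns X, per-variable column index list, and binary flag.
.encode_mixed <- function(md) {
  cols <- list(); X <- list()
  for (v in names(md$data)) {
    if (md$types[[v]] == "continuous") {
      X[[v]] <- matrix(md$data[[v]], ncol = 1L)
    } else {
      f <- md$data[[v]]
      L <- nlevels(f)
      d <- matrix(0, length(f), L - 1L)
      for (l in 2:L) d[, l - 1L] <- as.numeric(f == levels(f)[l])
      X[[v]] <- d
    }
  }
  sizes <- vapply(X, ncol, integer(1))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  for (v in names(X)) cols[[v]] <- seq(starts[[v]], stops[[v]])
  list(X = do.call(cbind, X), cols = cols)
}

# Test engine over one dataset: closure (x, y, Z) -> p-value, with x, y,
# Z variable names. Built once per learn; all linear tests run off the
# covariance matrix.
.ci_engine <- function(md) {
  enc <- .encode_mixed(md)
  X <- enc$X
  n <- nrow(X)
  S <- stats::cov(X)
  cols <- enc$cols
  types <- md$types
  data <- md$data

  cond_cov <- function(a, b) {
    # covariance of columns a given columns b
    if (!length(b)) return(S[a, a, drop = FALSE])
    S[a, a, drop = FALSE] -
      S[a, b, drop = FALSE] %*%
      solve(S[b, b, drop = FALSE], S[b, a, drop = FALSE])
  }

  function(x, y, Z = character(0)) {
    zc <- unlist(cols[Z], use.names = FALSE)
    if (n - length(zc) - 3 <= 0) return(0)  # conservative: dependent
    tx <- types[[x]]; ty <- types[[y]]
    if (tx == "continuous" && ty == "continuous") {
      C <- cond_cov(c(cols[[x]], cols[[y]]), zc)
      r <- C[1L, 2L] / sqrt(C[1L, 1L] * C[2L, 2L])
      r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
      zstat <- sqrt(n - length(zc) - 3) * atanh(r)
      return(2 * stats::pnorm(-abs(zstat)))
    }
    if (tx == "continuous" || ty == "continuous") {
      # continuous response, categorical partner: nested linear-model
      # deviance test via conditional variances
      resp <- if (tx == "continuous") x else y
      part <- if (tx == "continuous") y else x
      pc <- cols[[part]]
      v0 <- cond_cov(cols[[resp]], zc)[1L, 1L]
      v1 <- cond_cov(cols[[resp]], c(zc, pc))[1L, 1L]
      if (v1 <= 0 || v0 <= 0) return(0)
      stat <- n * log(v0 / v1)
      return(stats::pchisq(max(stat, 0), df = length(pc),
                           lower.tail = FALSE))
    }
    # categorical-categorical: logistic deviance (binary response only)
    fy <- data[[y]]
    if (nlevels(fy) > 2L && nlevels(data[[x]]) == 2L) {
      tmp <- x; x <- y; y <- tmp; fy <- data[[y]]
    }
    if (nlevels(fy) > 2L)
      stop("CI test between two multi-level categorical variables is ",
           "not supported", call. = FALSE)
    yy <- as.integer(fy == levels(fy)[2L])
    X0 <- cbind(1, X[, zc, drop = FALSE])
    X1 <- cbind(X0, X[, cols[[x]], drop = FALSE])
    f0 <- suppressWarnings(stats::glm.fit(X0, yy,
                                          family = stats::binomial()))
    f1 <- suppressWarnings(stats::glm.fit(X1, yy,
                                          family = stats::binomial()))
    stat <- f0$deviance - f1$deviance
    stats::pchisq(max(stat, 0), df = length(cols[[x]]),
                  lower.tail = FALSE)
  }
}

#' Conditional independence test for mixed data
#'
#' Dispatches on variable types: continuous-continuous uses the classical
#' partial-correlation Fisher-z test; continuous vs categorical uses a
#' nested linear-model deviance test with the continuous variable as
#' response; categorical-categorical (binary response) uses a logistic
#' deviance test. With too few rows for the conditioning set the pair is
#' conservatively declared dependent (`p = 0`).
#'
#' @param x,y Variable names.
#' @param Z Character vector of conditioning variable names.
#' @param data A [mixed_dataset()].
#' @param alpha Significance level; `independent` is `p >= alpha`.
#' @return List with `p` and `independent`.
#' @export
ci_test <- function(x, y, Z = character(0), data, alpha = 0.05) {
  stopifnot(inherits(data, "mixed_dataset"), x != y, !x %in% Z, !y %in% Z)
  p <- .ci_engine(data)(x, y, Z)
  list(p = p, independent = p >= alpha)
}

#' d-separation oracle over a known DAG
#'
#' @param adjacency Square 0/1 matrix with dimnames; `adj[i, j] = 1` for
#'   edge i -> j.
#' @return A function `(x, y, Z) -> p` returning 1 when x and y are
#'   d-separated by Z and 0 otherwise, usable as the `test` argument of
#'   [learn_pag()].
#' @export
dsep_oracle <- function(adjacency) {
  A <- adjacency
  vars <- rownames(A)
  force(A)
  function(x, y, Z = character(0)) {
    ok <- .dsep(A, x, y, Z)
    if (ok) 1 else 0
  }
}

# d-separation by ancestor moralization
.dsep <- function(A, x, y, Z) {
  vars <- rownames(A)
  anc <- unique(c(x, y, Z))
  repeat {
    pa <- vars[rowSums(A[, anc, drop = FALSE]) > 0]
    new <- setdiff(pa, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  Asub <- A[anc, anc, drop = FALSE]
  U <- (Asub + t(Asub)) > 0
  # moralize: connect co-parents
  for (v in anc) {
    pa <- anc[Asub[, v] > 0]
    if (length(pa) > 1L) U[pa, pa] <- TRUE
  }
  diag(U) <- FALSE
  keep <- setdiff(anc, Z)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  U <- U[keep, keep, drop = FALSE]
  # BFS from x
  reach <- setNames(rep(FALSE, length(keep)), keep)
  reach[x] <- TRUE
  queue <- x
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- keep[U[v, ]]
    new <- nb[!reach[nb]]
    reach[new] <- TRUE
    queue <- c(queue, new)
  }
  !reach[[y]]
}

# endpoint mark codes
.MARK_NONE <- 0L; .MARK_CIRCLE <- 1L; .MARK_ARROW <- 2L; .MARK_TAIL <- 3L

#' Learn a partial ancestral graph by constraint-based search
#'
#' PC-stable adjacency search (order-independent within each level, with
#' recorded separation sets), collider orientation from separation sets,
#' then FCI orientation rules R1-R4 applied to a fixpoint. Unresolved
#' endpoints remain circles. The possible-d-sep stage of full FCI is
#' omitted by default (desk-scale hybrid); `possible_dsep = TRUE` enables
#' an exhaustive extra removal pass suitable for small graphs.
#'
#' @param data A [mixed_dataset()] (ignored when `test` is supplied, save
#'   for variable names — pass `vars` then).
#' @param alpha Significance level for the CI tests.
#' @param max_cond_size Conditioning-set size cap (default 3).
#' @param test Optional CI oracle `(x, y, Z) -> p` (e.g. [dsep_oracle()]).
#' @param vars Variable names when `data` is NULL.
#' @param possible_dsep Exhaustive extra edge-removal pass over subsets of
#'   all remaining variables (for <= 10 nodes).
#' @return A `pag`: list with `nodes`, `marks` (matrix, `marks[i, j]` =
#'   endpoint at j on edge i-j: 0 none / 1 circle / 2 arrow / 3 tail) and
#'   `sepsets`.
#' @export
learn_pag <- function(data = NULL, alpha = 0.05, max_cond_size = 3L,
                      test = NULL, vars = NULL, possible_dsep = FALSE) {
  if (is.null(test)) {
    stopifnot(inherits(data, "mixed_dataset"))
    test <- .ci_engine(data)
    vars <- names(data$data)
  } else if (is.null(vars)) {
    stopifnot(inherits(data, "mixed_dataset") || is.character(vars))
    vars <- if (!is.null(data)) names(data$data) else vars
  }
  p <- length(vars)
  if (p < 3L) stop("need at least 3 variables", call. = FALSE)
  ord <- order(vars)  # name order for permutation invariance
  vars_sorted <- vars[ord]

  adj <- matrix(TRUE, p, p, dimnames = list(vars_sorted, vars_sorted))
  diag(adj) <- FALSE
  sepsets <- list()
  skey <- function(a, b) paste(sort(c(a, b)), collapse = "|")

  remove_pass <- function(adj, adj_source, l) {
    # one PC-stable level: adjacency frozen in adj_source
    for (xi in seq_len(p - 1L)) for (yi in (xi + 1L):p) {
      x <- vars_sorted[xi]; y <- vars_sorted[yi]
      if (!adj[x, y]) next
      cand <- list()
      nx <- vars_sorted[adj_source[x, ]]; nx <- setdiff(nx, y)
      ny <- vars_sorted[adj_source[y, ]]; ny <- setdiff(ny, x)
      if (length(nx) >= l) cand <- c(cand, list(nx))
      if (length(ny) >= l) cand <- c(cand, list(ny))
      removed <- FALSE
      tried <- character(0)
      for (nb in cand) {
        if (removed) break
        subs <- if (l == 0L) list(character(0)) else
          utils::combn(nb, l, simplify = FALSE)
        for (S in subs) {
          key <- paste(S, collapse = ",")
          if (key %in% tried) next
          tried <- c(tried, key)
          if (test(x, y, S) >= alpha) {
            adj[x, y] <- adj[y, x] <- FALSE
            sepsets[[skey(x, y)]] <<- S
            removed <- TRUE
            break
          }
        }
      }
    }
    adj
  }

  l <- 0L
  repeat {
    adj_source <- adj
    adj <- remove_pass(adj, adj_source, l)
    l <- l + 1L
    if (l > max_cond_size) break
    maxdeg <- max(rowSums(adj))
    if (maxdeg - 1L < l) break
  }

  if (possible_dsep) {
    # exhaustive removal over subsets of all other variables
    for (xi in seq_len(p - 1L)) for (yi in (xi + 1L):p) {
      x <- vars_sorted[xi]; y <- vars_sorted[yi]
      if (!adj[x, y]) next
      others <- setdiff(vars_sorted, c(x, y))
      for (l2 in 0:min(max_cond_size, length(others))) {
        subs <- if (l2 == 0L) list(character(0)) else
          utils::combn(others, l2, simplify = FALSE)
        done <- FALSE
        for (S in subs) {
          if (test(x, y, S) >= alpha) {
            adj[x, y] <- adj[y, x] <- FALSE
            sepsets[[skey(x, y)]] <- S
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
  }

  # endpoint marks: circles everywhere there is an edge
  mk <- matrix(.MARK_NONE, p, p, dimnames = dimnames(adj))
  mk[adj] <- .MARK_CIRCLE

  # collider orientation from sepsets (unshielded triples)
  for (z in vars_sorted) {
    nb <- vars_sorted[adj[z, ]]
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (k in seq_len(ncol(prs))) {
      x <- prs[1L, k]; y <- prs[2L, k]
      if (adj[x, y]) next
      S <- sepsets[[skey(x, y)]]
      if (is.null(S)) S <- character(0)
      if (!(z %in% S)) {
        mk[x, z] <- .MARK_ARROW
        mk[y, z] <- .MARK_ARROW
      }
    }
  }

  mk <- .fci_rules(mk, adj, sepsets, vars_sorted, skey)

  structure(list(nodes = vars_sorted, marks = mk, sepsets = sepsets,
                 alpha = alpha),
            class = "pag")
}

# FCI orientation rules R1-R4 applied to fixpoint.
.fci_rules <- function(mk, adj, sepsets, vars, skey) {
  p <- length(vars)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (b in vars) {
      nb_b <- vars[adj[b, ]]
      for (a in nb_b) for (c_ in nb_b) {
        if (a == c_) next
        # R1: a*->b o-* c, a,c non-adjacent => b -> c
        if (!adj[a, c_] && mk[a, b] == .MARK_ARROW &&
            mk[c_, b] == .MARK_CIRCLE) {
          mk[c_, b] <- .MARK_TAIL
          mk[b, c_] <- .MARK_ARROW
          changed <- TRUE
        }
      }
    }
    # R2: a -> b *-> c  or  a *-> b -> c, with a *-o c => a *-> c
    for (a in vars) for (c_ in vars) {
      if (a == c_ || !adj[a, c_] || mk[a, c_] != .MARK_CIRCLE) next
      for (b in vars[adj[a, ] & adj[, c_]]) {
        chain1 <- mk[a, b] == .MARK_ARROW && mk[b, a] == .MARK_TAIL &&
          mk[b, c_] == .MARK_ARROW
        chain2 <- mk[a, b] == .MARK_ARROW && mk[b, c_] == .MARK_ARROW &&
          mk[c_, b] == .MARK_TAIL
        if (chain1 || chain2) {
          mk[a, c_] <- .MARK_ARROW
          changed <- TRUE
          break
        }
      }
    }
    # R3: a*->b<-*c, a*-od o-*c, a,c non-adjacent, d*-ob => d*->b
    for (d in vars) for (b in vars[adj[d, ]]) {
      if (mk[d, b] != .MARK_CIRCLE) next
      nb <- vars[adj[d, ] & adj[, b]]
      hit <- FALSE
      for (a in nb) {
        if (hit) break
        for (c_ in nb) {
          if (a == c_ || adj[a, c_]) next
          if (mk[a, b] == .MARK_ARROW && mk[c_, b] == .MARK_ARROW &&
              mk[a, d] == .MARK_CIRCLE && mk[c_, d] == .MARK_CIRCLE) {
            mk[d, b] <- .MARK_ARROW
            changed <- TRUE
            hit <- TRUE
            break
          }
        }
      }
    }
    # R4: discriminating paths
    for (c_ in vars) for (v in vars[adj[, c_]]) {
      if (mk[v, c_] == .MARK_NONE || mk[c_, v] != .MARK_CIRCLE) next
      # candidates w: collider on path, parent of c
      for (w in vars[adj[, v] & adj[, c_]]) {
        if (w == c_ || w == v) next
        if (!(mk[w, c_] == .MARK_ARROW && mk[c_, w] == .MARK_TAIL)) next
        if (mk[v, w] != .MARK_ARROW) next
        theta <- .find_disc_origin(mk, adj, vars, w, v, c_)
        if (is.null(theta)) next
        S <- sepsets[[skey(theta, c_)]]
        if (!is.null(S) && v %in% S) {
          mk[c_, v] <- .MARK_TAIL
          mk[v, c_] <- .MARK_ARROW
        } else {
          mk[w, v] <- .MARK_ARROW
          mk[v, w] <- .MARK_ARROW
          mk[v, c_] <- .MARK_ARROW
          mk[c_, v] <- .MARK_ARROW
        }
        changed <- TRUE
        break
      }
    }
  }
  mk
}

# search for the origin theta of a discriminating path <theta,...,w,v,c>:
# walk back from w through colliders that are parents of c; return theta
# (non-adjacent to c) or NULL.
.find_disc_origin <- function(mk, adj, vars, w, v, c_, depth = 0L) {
  if (depth > length(vars)) return(NULL)
  for (q in vars[adj[, w]]) {
    if (q %in% c(v, c_)) next
    if (mk[q, w] != .MARK_ARROW) next  # q *-> w
    if (!adj[q, c_]) return(q)         # theta found
    # q must itself be a collider and a parent of c to extend the path
    if (mk[w, q] == .MARK_ARROW &&
        mk[q, c_] == .MARK_ARROW && mk[c_, q] == .MARK_TAIL) {
      res <- .find_disc_origin(mk, adj, vars, q, w, c_, depth + 1L)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

#' @export
print.pag <- function(x, ...) {
  e <- pag_edges(x)
  cat(sprintf("<pag> %d nodes, %d edges (alpha = %s)\n", length(x$nodes),
              nrow(e), format(x$alpha)))
  if (nrow(e)) {
    for (i in seq_len(nrow(e)))
      cat(" ", e$from[i], e$type[i], e$to[i], "\n")
  }
  invisible(x)
}

#' Edge list of a PAG with endpoint marks
#'
#' @param pag A `pag`.
#' @return Data.frame with `from`, `to`, `end_from`, `end_to` (`circle`,
#'   `arrow`, `tail`) and a display `type` (`-->`, `<->`, `o->`, `o-o`,
#'   ...).
#' @export
pag_edges <- function(pag) {
  mk <- pag$marks
  vars <- pag$nodes
  sym <- c("?", "o", ">", "-")  # index mark+1; left side mirrored
  rows <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    if (mk[i, j] == .MARK_NONE) next
    m_i <- mk[j, i]  # mark at i
    m_j <- mk[i, j]  # mark at j
    lsym <- c("?", "o", "<", "-")[m_i + 1L]
    rsym <- c("?", "o", ">", "-")[m_j + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      from = vars[i], to = vars[j],
      end_from = c("none", "circle", "arrow", "tail")[m_i + 1L],
      end_to = c("none", "circle", "arrow", "tail")[m_j + 1L],
      type = paste0(lsym, "-", rsym), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(from = character(0), to = character(0),
                      end_from = character(0), end_to = character(0),
                      type = character(0)))
  do.call(rbind, rows)
}

#' Skeleton adjacency matrix of a PAG
#' @param pag A `pag`.
#' @return Logical adjacency matrix.
#' @export
pag_skeleton <- function(pag) pag$marks != .MARK_NONE

#' Markov blanket of a target in a PAG
#'
#' Possible parents and children (all adjacent nodes, circle endpoints
#' read inclusively) plus spouses: nodes with an arrowhead into a common
#' possible child of the target.
#'
#' @param pag A `pag`.
#' @param target Node name.
#' @return Character vector of variable names.
#' @export
markov_blanket <- function(pag, target) {
  if (!target %in% pag$nodes) stop("target not in graph", call. = FALSE)
  mk <- pag$marks
  adj <- mk != .MARK_NONE
  nb <- pag$nodes[adj[target, ]]
  # possible children: adjacent c with arrow-or-circle at c from target
  children <- nb[mk[target, nb] %in% c(.MARK_ARROW, .MARK_CIRCLE)]
  spouses <- character(0)
  for (c_ in children) {
    cand <- pag$nodes[adj[, c_]]
    cand <- setdiff(cand, c(target, nb))
    spouses <- c(spouses, cand[mk[cand, c_] == .MARK_ARROW])
  }
  sort(unique(c(nb, spouses)))
}

#' Nested leave-one-out cross-validated alpha selection
#'
#' For each candidate alpha and each left-out row: a PAG is learned on
#' the remaining rows, the Markov blanket of the target extracted, a
#' logistic regression of the target on the blanket fitted and the
#' left-out row predicted. Per-alpha ROC AUC over all rows decides;
#' ties go to the smallest alpha (sparser graphs). Empty blankets fall
#' back to an intercept-only prediction.
#'
#' @param data A [mixed_dataset()]; target must be binary categorical.
#' @param target Target variable name.
#' @param grid Alpha grid (default `c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25)`).
#' @param max_cond_size Conditioning-set cap passed to [learn_pag()].
#' @return An `alpha_selection`: list with `grid`, `auc` (per alpha),
#'   `chosen`, `mb_full` (blanket on the full data at the chosen alpha)
#'   and `mb_traces` (per-alpha membership frequency over folds).
#' @export
select_alpha <- function(data, target,
                         grid = c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25),
                         max_cond_size = 3L) {
  stopifnot(inherits(data, "mixed_dataset"))
  if (data$types[[target]] != "categorical" ||
      nlevels(data$data[[target]]) != 2L)
    stop("target must be binary", call. = FALSE)
  n <- data$n
  yfull <- as.integer(data$data[[target]] ==
                        levels(data$data[[target]])[2L])
  vars <- names(data$data)

  enc_full <- .encode_mixed(data)
  aucs <- numeric(length(grid))
  traces <- matrix(0, length(grid), length(vars),
                   dimnames = list(format(grid), vars))
  for (gi in seq_along(grid)) {
    a <- grid[gi]
    preds <- numeric(n)
    for (i in seq_len(n)) {
      di <- mixed_dataset(data$data[-i, , drop = FALSE], data$types,
                          standardize = FALSE)
      g <- learn_pag(di, alpha = a, max_cond_size = max_cond_size)
      mb <- markov_blanket(g, target)
      traces[gi, mb] <- traces[gi, mb] + 1 / n
      ytr <- yfull[-i]
      if (!length(mb)) {
        preds[i] <- mean(ytr)
        next
      }
      mbc <- unlist(enc_full$cols[mb], use.names = FALSE)
      Xtr <- cbind(1, enc_full$X[-i, mbc, drop = FALSE])
      fit <- suppressWarnings(stats::glm.fit(Xtr, ytr,
                                             family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      eta <- sum(c(1, enc_full$X[i, mbc]) * cf)
      preds[i] <- stats::plogis(eta)
    }
    aucs[gi] <- auc_mw(preds, yfull)
  }
  best <- which(aucs == max(aucs))
  chosen <- grid[best[which.min(grid[best])]]
  gfull <- learn_pag(data, alpha = chosen, max_cond_size = max_cond_size)
  structure(list(grid = grid, auc = aucs, chosen = chosen,
                 mb_full = markov_blanket(gfull, target),
                 mb_traces = traces, pag = gfull),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat("<alpha_selection> chosen alpha =", x$chosen, "\n")
  print(data.frame(alpha = x$grid, auc = round(x$auc, 4)))
  invisible(x)
}

#' Serialise a PAG as a JSON edge list
#'
#' @param pag A `pag`.
#' @param path Output JSON path.
#' @export
write_pag <- function(pag, path) {
  jsonlite::write_json(list(nodes = pag$nodes, edges = pag_edges(pag),
                            alpha = pag$alpha),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
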