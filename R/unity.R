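#' Bell numbers
#'
#' Exact count of set partitions of `n` elements, via the Bell triangle
#' recurrence.
#'
#' @param n Non-negative integer.
#' @return The Bell number `B_n` (as a double; exact for the sizes this
#'   package enumerates).
#' @examples
#' bell_number(6) # 203
#' @export
bell_number <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return(1)
  row <- 1
  for (i in seq_len(n - 1)) {
    new_row <- numeric(i + 1)
    new_row[1] <- row[i]
    for (j in seq_len(i)) new_row[j + 1] <- new_row[j] + row[j]
    row <- new_row
  }
  row[length(row)]
}

#' Enumerate all nontrivial partitions of a node set
#'
#' Every way of viewing the system as two or more disjoint covering
#' subsystems: all set partitions except the one-block partition. Canonical
#' order: partitions are generated as restricted-growth strings in
#' lexicographic order, which sorts blocks by smallest member.
#'
#' @param nodes Character vector of node names, or an integer count
#'   (names `1..n` are used).
#' @return A list of `B_n - 1` partitions, each a list of character
#'   vectors (the blocks).
#' @examples
#' length(enumerate_partitions(4)) # 14
#' @export
enumerate_partitions <- function(nodes) {
  if (is.numeric(nodes) && length(nodes) == 1L) {
    nodes <- as.character(seq_len(nodes))
  }
  n <- length(nodes)
  if (n < 2L || n > 12L) stop("partition enumeration supports 2..12 nodes")
  out <- vector("list", bell_number(n) - 1)
  cnt <- 0L
  a <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      if (mx > 0L) {  # skip the one-block partition
        cnt <<- cnt + 1L
        out[[cnt]] <<- unname(split(nodes, a))
      }
      return(invisible())
    }
    for (v in 0:(mx + 1L)) {
      a[i] <<- v
      rec(i + 1L, max(mx, v))
    }
  }
  rec(2L, 0L)
  out
}

partition_label <- function(partition) {
  paste(vapply(partition, function(b) paste0("{", paste(b, collapse = ","), "}"),
               ""), collapse = " | ")
}

subsystem_key <- function(node_names, strict = FALSE) {
  paste0(paste(sort(node_names), collapse = "|"), if (strict) "#strict")
}

key_hash <- function(key) {
  v <- utf8ToInt(key)
  sum(v * seq_along(v)) %% 100003
}

restrict_data <- function(data, nodes) {
  if (inherits(data, "efe_obs")) restrict_observations(data, nodes)
  else marginalize(data, nodes)
}

# remap levels of restricted data onto the compact effective value set V_X
compact_levels <- function(sub) {
  used <- if (inherits(sub, "efe_obs")) sort(unique(as.vector(sub$states)))
          else effective_values(sub, sub$spec$nodes)
  m <- sub$spec$m
  if (length(used) == m) return(list(data = sub, level_map = NULL))
  level_map <- rep(NA_integer_, m)
  level_map[used + 1L] <- seq_along(used) - 1L
  spec2 <- efe_system(sub$spec$nodes, length(used))
  if (inherits(sub, "efe_obs")) {
    st <- matrix(level_map[sub$states + 1L], nrow = nrow(sub$states))
    list(data = observations(st, spec2), level_map = level_map)
  } else {
    states <- enumerate_states(sub$spec)
    keep <- which(sub$p > 0)
    st <- matrix(level_map[states[keep, , drop = FALSE] + 1L],
                 nrow = length(keep))
    p2 <- numeric(length(used)^length(spec2$nodes))
    idx2 <- state_index(st, length(used))
    acc <- rowsum(sub$p[keep], idx2)
    p2[as.integer(rownames(acc))] <- acc[, 1]
    list(data = distribution(p2, spec2), level_map = level_map)
  }
}

# minimised EFE (and model) of a subsystem, memoised by node set.
# Singletons use the closed form log2 m: with no off-diagonal node pairs
# every state has zero discontinuity, so the accessible set is the whole
# (possibly compacted) level set.
subsystem_fit <- function(data, nodes, control, cache, strict = FALSE) {
  idx <- resolve_subsystem(data$spec, nodes)
  key <- subsystem_key(data$spec$nodes[idx], strict)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  sub <- restrict_data(data, idx)
  level_map <- NULL
  if (strict) {
    cl <- compact_levels(sub)
    sub <- cl$data
    level_map <- cl$level_map
  }
  fit <- efe_fit(sub, control = control)
  entry <- list(nodes = data$spec$nodes[idx], efe_min = fit$efe_min,
                model = fit$model, level_map = level_map,
                converged = fit$converged, closed_form = isTRUE(fit$closed_form),
                degenerate = fit$degenerate)
  cache[[key]] <- entry
  entry
}

#' Collective EFE excess of a partition
#'
#' For a partition of the node set into subsystems, the sum of the
#' per-block minimised EFEs minus the whole-system minimised EFE (each
#' term individually minimised over primary models). Negative values mean
#' the decomposition beats a single whole-system model.
#'
#' @param partition A list of blocks (node-name or index vectors) covering
#'   the system disjointly.
#' @param data An `efe_obs` or `efe_distribution`.
#' @param control An [efe_control()] used for every block optimisation.
#' @param cache Optional environment memoising subsystem fits.
#' @param strict_vx Recompute each block's effective level set and shrink
#'   its state space (the contrived `V_X != V` case); default uses the full
#'   level set for every block.
#' @return The value in bits.
#' @export
mu <- function(partition, data, control = efe_control(), cache = NULL,
               strict_vx = FALSE) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  whole <- subsystem_fit(data, data$spec$nodes, control, cache, FALSE)
  block_sum <- sum(vapply(partition, function(b) {
    subsystem_fit(data, b, control, cache, strict_vx)$efe_min
  }, 0))
  block_sum - whole$efe_min
}

# per-block accessible-set counts at the support states, plus whole-system
# counts, for the ratio identity and the product bound
mu_ratio_counts <- function(partition, data, block_entries, whole_model,
                            eps_tie = 1e-9) {
  P <- if (inherits(data, "efe_obs")) empirical_distribution(data) else data
  spec <- P$spec
  states <- enumerate_states(spec)
  support <- which(P$p > 0)
  w <- P$p[support]
  d_s <- d_profile_cpp(states, whole_model$R, whole_model$U)
  sorted_s <- sort(d_s)
  count_s <- findInterval(d_s[support] + eps_tie, sorted_s)
  block_counts <- matrix(0, nrow = length(support), ncol = length(partition))
  for (bi in seq_along(partition)) {
    idx <- resolve_subsystem(spec, partition[[bi]])
    entry <- block_entries[[bi]]
    sub_states <- states[support, idx, drop = FALSE]
    if (!is.null(entry$level_map)) {
      sub_states <- matrix(entry$level_map[sub_states + 1L],
                           nrow = nrow(sub_states))
      mb <- nrow(entry$model$U)
    } else {
      mb <- spec$m
    }
    bstates <- enumerate_states(length(idx), m = mb)
    d_b <- d_profile_cpp(bstates, entry$model$R, entry$model$U)
    sorted_b <- sort(d_b)
    bidx <- state_index(sub_states, mb)
    block_counts[, bi] <- findInterval(d_b[bidx] + eps_tie, sorted_b)
  }
  list(weight = w, block_counts = block_counts, whole_counts = count_s,
       n_states = nrow(states))
}

#' Collective EFE excess via the accessible-set ratio identity
#'
#' Computes the same quantity as [mu()] through the equivalent expectation
#' of `log2(|A_partition(f)| / |A_whole(f)|)` over the system distribution,
#' where `|A_partition(f)|` is the product of the blocks' accessible-set
#' sizes at `f`'s restrictions. Uses the optimal models already fixed in a
#' [unity_analysis()] report, so the two routes agree to floating-point
#' precision.
#'
#' @param report A `unity_report`.
#' @param partition A partition (list of blocks) or an index into
#'   `report$partitions`.
#' @return The value in bits.
#' @export
mu_ratio <- function(report, partition) {
  stopifnot(inherits(report, "unity_report"))
  if (is.numeric(partition)) partition <- report$partitions[[partition]]
  entries <- lapply(partition, function(b) {
    key <- subsystem_key(as.character(b), report$strict_vx)
    entry <- report$cache[[key]]
    if (is.null(entry)) {
      entry <- subsystem_fit(report$data, b, report$control, report$cache,
                             report$strict_vx)
    }
    entry
  })
  cc <- mu_ratio_counts(partition, report$data, entries,
                        report$whole$model, report$control$eps_tie)
  sum(cc$weight * (rowSums(log2(cc$block_counts)) - log2(cc$whole_counts)))
}

#' Model-unity analysis of a system
#'
#' Fits an EFE-minimising primary model to every proper subsystem of the
#' node set (memoised: at most `2^n - 2` optimisations; singleton blocks
#' use the closed form `log2 m`) and to the whole system, evaluates the
#' collective EFE excess `mu` of every nontrivial partition, and takes the
#' minimum `M`. The system has model unity iff `M >= 0` (within
#' `eps_unity`, since computed minima carry optimiser noise): no
#' decomposition of the system into separately modelled subsystems beats a
#' single model stretched across the whole system.
#'
#' @param data An `efe_obs` or `efe_distribution`.
#' @param nodes Optional subsystem to analyse (defaults to the full node
#'   set); the analysis then concerns partitions of that subsystem of the
#'   restricted data.
#' @param control An [efe_control()] governing every optimisation.
#' @param eps_unity Tolerance for the `M >= 0` decision and for argmin
#'   ties.
#' @param strict_vx Shrink block state spaces to effective level sets (see
#'   [mu()]).
#' @param cache Optional environment of memoised subsystem fits (shared
#'   across analyses of the same data).
#' @param lemma1 Verify on the computed argmin that every multi-node block
#'   itself has model unity (a theorem; violations flag optimiser failure).
#' @return An object of class `unity_report`; see Details.
#' @details The report contains `M`, `has_unity`, `mu` (one value per
#'   partition of the canonical enumeration in `partitions`), `argmin`
#'   (all partitions within `eps_unity` of `M`), `whole` (the whole-system
#'   fit), `cache` (per-subsystem fits), and `lemma1` (check results, when
#'   requested).
#' @examples
#' obs <- observations(rbind(c(0, 0), c(1, 1)), efe_system(2, 2))
#' rep <- unity_analysis(obs, control = efe_control(restarts = 4))
#' rep$M
#' @export
unity_analysis <- function(data, nodes = NULL, control = efe_control(),
                           eps_unity = 1e-6, strict_vx = FALSE, cache = NULL,
                           lemma1 = TRUE) {
  stopifnot(inherits(data, "efe_obs") || inherits(data, "efe_distribution"))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(nodes)) nodes <- data$spec$nodes
  idx <- resolve_subsystem(data$spec, nodes)
  node_names <- data$spec$nodes[idx]
  if (length(node_names) < 2L) stop("unity analysis needs at least 2 nodes")

  whole <- subsystem_fit(data, node_names, control, cache, FALSE)
  partitions <- enumerate_partitions(node_names)
  mu_values <- vapply(partitions, function(p) {
    sum(vapply(p, function(b) {
      subsystem_fit(data, b, control, cache, strict_vx)$efe_min
    }, 0)) - whole$efe_min
  }, 0)
  names(mu_values) <- vapply(partitions, partition_label, "")
  M <- min(mu_values)
  argmin_index <- which(mu_values <= M + eps_unity)
  report <- structure(list(
    M = M, has_unity = M >= -eps_unity, eps_unity = eps_unity,
    mu = mu_values, partitions = partitions,
    argmin = partitions[argmin_index], argmin_index = argmin_index,
    whole = whole, nodes = node_names, spec = data$spec, data = data,
    control = control, strict_vx = strict_vx, cache = cache,
    lemma1 = NULL), class = "unity_report")
  if (lemma1) report$lemma1 <- verify_lemma1(report)
  report
}

#' Verify the first lemma of model unity on a computed argmin
#'
#' The lemma: every multi-node block of a mu-minimising partition itself
#' has model unity, and when `M < 0` with a unique argmin, no proper union
#' of two or more argmin blocks has model unity. Both statements are
#' theorems, so any reported counterexample falsifies the optimisation
#' (insufficient budget), not the lemma.
#'
#' @param report A `unity_report`.
#' @return A list with `ok`, `blocks` (data frame of multi-node argmin
#'   blocks and their `M` values) and `unions` (data frame of checked
#'   block unions, when applicable).
#' @export
verify_lemma1 <- function(report) {
  stopifnot(inherits(report, "unity_report"))
  eps <- report$eps_unity
  block_rows <- list()
  for (p in report$argmin) {
    for (b in p) {
      if (length(b) > 1L) {
        key <- subsystem_key(as.character(b))
        if (!is.null(block_rows[[key]])) next
        sub_rep <- unity_analysis(report$data, nodes = b,
                                  control = report$control, eps_unity = eps,
                                  strict_vx = report$strict_vx,
                                  cache = report$cache, lemma1 = FALSE)
        block_rows[[key]] <- data.frame(block = partition_label(list(b)),
                                        M = sub_rep$M,
                                        has_unity = sub_rep$has_unity)
      }
    }
  }
  blocks <- if (length(block_rows)) do.call(rbind, unname(block_rows))
            else data.frame(block = character(0), M = numeric(0),
                            has_unity = logical(0))
  unions <- NULL
  if (report$M < -eps && length(report$argmin) == 1L) {
    part <- report$argmin[[1L]]
    nb <- length(part)
    union_rows <- list()
    if (nb >= 3L) {
      for (r in 2:(nb - 1L)) {
        combos <- utils::combn(nb, r, simplify = FALSE)
        for (cmb in combos) {
          un <- sort(unlist(part[cmb]))
          sub_rep <- unity_analysis(report$data, nodes = un,
                                    control = report$control,
                                    eps_unity = eps,
                                    strict_vx = report$strict_vx,
                                    cache = report$cache, lemma1 = FALSE)
          union_rows[[length(union_rows) + 1L]] <-
            data.frame(union = partition_label(list(un)), M = sub_rep$M,
                       has_unity = sub_rep$has_unity)
        }
      }
    }
    unions <- if (length(union_rows)) do.call(rbind, union_rows)
              else data.frame(union = character(0), M = numeric(0),
                              has_unity = logical(0))
  }
  ok <- all(blocks$has_unity) &&
    (is.null(unions) || !any(unions$has_unity))
  list(ok = ok, blocks = blocks, unions = unions)
}

#' @export
print.unity_report <- function(x, ...) {
  cat("Model-unity analysis: ", length(x$nodes), " nodes, ",
      length(x$partitions), " partitions\n", sep = "")
  cat("  whole-system efe_min: ", format(x$whole$efe_min, digits = 6),
      " bits\n", sep = "")
  cat("  M = ", format(x$M, digits = 6), " bits -> ",
      if (x$has_unity) "model unity" else "NO model unity", "\n", sep = "")
  cat("  argmin: ", partition_label(x$argmin[[1]]),
      if (length(x$argmin) > 1) sprintf(" (and %d ties)",
                                        length(x$argmin) - 1), "\n", sep = "")
  if (!is.null(x$lemma1)) {
    cat("  lemma-1 check: ", if (x$lemma1$ok) "passed" else "FAILED",
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.unity_report <- function(object, n_show = 5, ...) {
  print(object)
  ord <- order(object$mu)
  cat("  lowest mu values:\n")
  for (i in ord[seq_len(min(n_show, length(ord)))]) {
    cat(sprintf("    %-40s %s\n", names(object$mu)[i],
                format(object$mu[i], digits = 6)))
  }
  invisible(object)
}

#' Plot the mu profile of a unity analysis
#'
#' Partitions along the x-axis ordered by increasing `mu`; the sign of the
#' lowest point decides model unity.
#'
#' @param x A `unity_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.unity_report <- function(x, ...) {
  mu_sorted <- sort(x$mu)
  graphics::plot(seq_along(mu_sorted), mu_sorted, pch = 20,
                 xlab = "partitions (ordered by mu)", ylab = "mu (bits)",
                 ...)
  graphics::abline(h = 0, col = "grey50", lty = 2)
  graphics::points(1, mu_sorted[1], col = "red", pch = 19)
  invisible(x)
}

# M of a subsystem from an already-populated cache (arithmetic only when
# all needed subsets are cached; fits any missing subset otherwise)
subsystem_M <- function(report, nodes) {
  idx <- resolve_subsystem(report$spec, nodes)
  node_names <- report$spec$nodes[idx]
  if (length(node_names) < 2L) return(Inf)  # singletons: unity by convention
  whole <- subsystem_fit(report$data, node_names, report$control,
                         report$cache, FALSE)
  parts <- enumerate_partitions(node_names)
  min(vapply(parts, function(p) {
    sum(vapply(p, function(b) {
      subsystem_fit(report$data, b, report$control, report$cache,
                    report$strict_vx)$efe_min
    }, 0)) - whole$efe_min
  }, 0))
}

all_subsets <- function(n, min_size = 1L, max_size = n) {
  out <- list()
  for (r in min_size:max_size) {
    out <- c(out, utils::combn(n, r, simplify = FALSE))
  }
  out
}

#' Maximal subsystems with model unity
#'
#' A subsystem is maximal if it has model unity but every strict superset
#' lacks it. A system with model unity has exactly one maximal subsystem:
#' itself. For systems without unity, when the maximal subsystems are
#' pairwise disjoint and the mu argmin is unique, they coincide with the
#' argmin partition's blocks (the second lemma of model unity), which is
#' checked and reported.
#'
#' @param x A `unity_report`, or data accepted by [unity_analysis()].
#' @param control Used only when `x` is data.
#' @param ... Passed to [unity_analysis()] when `x` is data.
#' @return An object of class `maximal_subsystems`: list with `subsystems`
#'   (list of node vectors), `M_values`, `disjoint`, `lemma2` (`NA` when
#'   not applicable, else whether the maximal set equals the argmin
#'   blocks) and `singletons` (nodes only trivially unified, flagged
#'   separately).
#' @export
maximal_subsystems <- function(x, control = efe_control(), ...) {
  report <- if (inherits(x, "unity_report")) x
            else unity_analysis(x, control = control, ...)
  n <- length(report$nodes)
  if (n > 8L) stop("maximal-subsystem scan supports at most 8 nodes")
  eps <- report$eps_unity
  subsets <- all_subsets(n, min_size = 2L, max_size = n)
  keys <- vapply(subsets, function(s) paste(s, collapse = ","), "")
  M_vals <- vapply(subsets, function(s) {
    if (length(s) == n) report$M else subsystem_M(report, report$nodes[s])
  }, 0)
  unified <- M_vals >= -eps
  names(unified) <- keys
  is_maximal <- vapply(seq_along(subsets), function(i) {
    if (!unified[i]) return(FALSE)
    s <- subsets[[i]]
    if (length(s) == n) return(TRUE)
    others <- setdiff(seq_len(n), s)
    for (o in others) {
      sup <- sort(c(s, o))
      if (unified[paste(sup, collapse = ",")]) return(FALSE)
    }
    # a unified superset of any size implies a unified one-node extension
    # need not exist; check all strict supersets
    for (j in seq_along(subsets)) {
      sj <- subsets[[j]]
      if (length(sj) > length(s) && all(s %in% sj) && unified[j]) {
        return(FALSE)
      }
    }
    TRUE
  }, TRUE)
  max_sets <- lapply(subsets[is_maximal], function(s) report$nodes[s])
  max_M <- M_vals[is_maximal]
  disjoint <- {
    all_nodes <- unlist(max_sets)
    !anyDuplicated(all_nodes)
  }
  lemma2 <- NA
  if (!report$has_unity && disjoint && length(report$argmin) == 1L) {
    arg_blocks <- lapply(report$argmin[[1L]], sort)
    found <- lapply(max_sets, sort)
    lemma2 <- setequal(vapply(arg_blocks, paste, "", collapse = ","),
                       vapply(found, paste, "", collapse = ","))
  }
  covered <- unique(unlist(max_sets))
  structure(list(subsystems = max_sets, M_values = max_M,
                 disjoint = disjoint, lemma2 = lemma2,
                 singletons = setdiff(report$nodes, covered),
                 report_M = report$M),
            class = "maximal_subsystems")
}

#' @export
print.maximal_subsystems <- function(x, ...) {
  cat("Maximal subsystems with model unity:\n")
  for (i in seq_along(x$subsystems)) {
    cat("  {", paste(x$subsystems[[i]], collapse = ","), "}  M = ",
        format(x$M_values[i], digits = 6), "\n", sep = "")
  }
  if (length(x$singletons)) {
    cat("  singletons (trivially unified): ",
        paste(x$singletons, collapse = ", "), "\n", sep = "")
  }
  cat("  pairwise disjoint: ", x$disjoint, "\n", sep = "")
  if (!is.na(x$lemma2)) {
    cat("  lemma-2 (maximal = argmin blocks): ", x$lemma2, "\n", sep = "")
  }
  invisible(x)
}

#' Survey the transitivity of model unity
#'
#' For disjoint nonempty subsystems X, Y, Z with both X∪Y and Y∪Z unified,
#' reports whether X∪Y∪Z is unified. This is an empirical survey (unity is
#' expected to be biased toward, but not guaranteed, transitivity), so no
#' pass/fail verdict is attached.
#'
#' @param x A `unity_report`, or data accepted by [unity_analysis()].
#' @param control Used only when `x` is data.
#' @param ... Passed to [unity_analysis()] when `x` is data.
#' @return A data frame with one row per qualifying (X, Y, Z) triple
#'   (unordered in X, Z) and columns `X`, `Y`, `Z`, `union_unified`.
#' @export
check_transitivity <- function(x, control = efe_control(), ...) {
  report <- if (inherits(x, "unity_report")) x
            else unity_analysis(x, control = control, ...)
  n <- length(report$nodes)
  if (n > 6L) stop("transitivity scan supports at most 6 nodes")
  eps <- report$eps_unity
  unified_memo <- new.env(parent = emptyenv())
  unified <- function(s) {
    key <- paste(s, collapse = ",")
    hit <- unified_memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (length(s) < 2L) TRUE
           else subsystem_M(report, report$nodes[s]) >= -eps
    unified_memo[[key]] <- val
    val
  }
  rows <- list()
  for (code in 0:(4^n - 1)) {
    digits <- (code %/% 4^(seq_len(n) - 1)) %% 4
    X <- which(digits == 1); Y <- which(digits == 2); Z <- which(digits == 3)
    if (!length(X) || !length(Y) || !length(Z)) next
    if (min(X) > min(Z)) next  # X, Z unordered
    if (!unified(sort(c(X, Y))) || !unified(sort(c(Y, Z)))) next
    rows[[length(rows) + 1L]] <- data.frame(
      X = paste(report$nodes[X], collapse = ","),
      Y = paste(report$nodes[Y], collapse = ","),
      Z = paste(report$nodes[Z], collapse = ","),
      union_unified = unified(sort(c(X, Y, Z))))
  }
  if (!length(rows)) {
    return(data.frame(X = character(0), Y = character(0), Z = character(0),
                      union_unified = logical(0)))
  }
  do.call(rbind, rows)
}

#' Mode distance between two system distributions
#'
#' The L1 distance between the full mu profiles of two datasets over the
#' same node set: `sum over partitions of |mu(X, A) - mu(X, B)|`. A probe
#' of how a shift in the system's bias moves its unity structure. It is a
#' pseudometric: non-negative, symmetric, and satisfies the triangle
#' inequality.
#'
#' @param a,b `efe_obs` or `efe_distribution` objects over identical
#'   systems, or two `unity_report`s.
#' @param control An [efe_control()] used for both analyses.
#' @param ... Passed to [unity_analysis()].
#' @return Distance in bits, with the two reports as attributes.
#' @export
mode_distance <- function(a, b, control = efe_control(), ...) {
  rep_a <- if (inherits(a, "unity_report")) a
           else unity_analysis(a, control = control, lemma1 = FALSE, ...)
  rep_b <- if (inherits(b, "unity_report")) b
           else unity_analysis(b, control = control, lemma1 = FALSE, ...)
  if (!identical(rep_a$nodes, rep_b$nodes) ||
      rep_a$spec$m != rep_b$spec$m) {
    stop("the two datasets must share the same system")
  }
  structure(sum(abs(rep_a$mu - rep_b$mu)),
            report_a = rep_a, report_b = rep_b)
}
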