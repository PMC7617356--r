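# Multi-objective symbolic-regression engine: NSGA-II style evolution of
# expression trees, minimising (binary cross-entropy, 1 - F1).

#' Evolution parameters
#'
#' Defaults follow the published protocol where stated (population 300,
#' 500 generations, two objectives) and standard genetic-programming
#' practice elsewhere (ramped half-and-half initialisation at depths 2-6,
#' maximum depth 17, subtree crossover probability 0.8, mutation 0.2,
#' binary tournament on (rank, crowding distance), elitist mu+lambda
#' survival).
#'
#' @param population Population size (default 300).
#' @param generations Number of generations (default 500).
#' @param p_crossover Subtree-crossover probability.
#' @param p_mutation Mutation probability per offspring.
#' @param tournament Tournament size.
#' @param max_depth Maximum tree depth.
#' @param init_depth Ramped initialisation depth range.
#' @param const_range Ephemeral-constant range (features are 0-1 scaled).
#' @param threshold Classification threshold for the F1 objective.
#' @param objective `"multi"` (BCE and 1-F1) or `"bce"` (single-objective
#'   baseline used to demonstrate the value of the F1 objective).
#' @param seed Master seed; all randomness flows from named substreams.
#' @return list of class `evolution_params`.
#' @export
evolution_params <- function(population = 300, generations = 500,
                             p_crossover = 0.8, p_mutation = 0.2,
                             tournament = 2, max_depth = 17,
                             init_depth = c(2, 6), const_range = c(-2, 2),
                             threshold = 0.5,
                             objective = c("multi", "bce"), seed = 1) {
  objective <- match.arg(objective)
  stopifnot(population >= 2, generations >= 0,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(population = population, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 tournament = tournament, max_depth = max_depth,
                 init_depth = init_depth, const_range = const_range,
                 threshold = threshold, objective = objective, seed = seed),
            class = "evolution_params")
}

#' Predicted class probability from a tree's raw score
#'
#' Logistic link from the raw formula output to a probability in (0, 1).
#'
#' @param tree Expression tree.
#' @param X Feature matrix (or `feature_matrix`).
#' @return Probability vector.
#' @export
predict_probability <- function(tree, X) {
  stats::plogis(eval_tree(tree, X))
}

#' The two optimisation objectives for one tree
#'
#' Binary cross-entropy with probabilities clipped to [1e-12, 1 - 1e-12],
#' and the complement of F1 at the classification threshold. Both are
#' minimised.
#'
#' @param tree Expression tree.
#' @param X Feature matrix.
#' @param labels 0/1 outcome vector with both classes present.
#' @param threshold Classification threshold (default 0.5).
#' @return c(bce = ..., f1_complement = ...).
#' @export
objectives <- function(tree, X, labels, threshold = 0.5) {
  if (length(unique(labels)) < 2)
    stop("objectives need both outcome classes present")
  p <- predict_probability(tree, X)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  cts <- confusion(labels, p, threshold)
  f1 <- if (2 * cts$TP + cts$FP + cts$FN == 0) 0
        else 2 * cts$TP / (2 * cts$TP + cts$FP + cts$FN)
  c(bce = bce, f1_complement = 1 - f1)
}

#' Fast non-dominated sort (minimisation on every objective)
#'
#' `a` dominates `b` iff `a <= b` componentwise with strict inequality
#' somewhere. Front k holds the individuals dominated only by members of
#' fronts < k.
#'
#' @param objs Numeric matrix, one row per individual.
#' @return list of integer index vectors, one per front.
#' @export
non_dominated_sort <- function(objs) {
  n <- nrow(objs)
  if (n == 0) return(list())
  # dom[i, j]: i dominates j, built by vectorised pairwise comparison
  le_all <- matrix(TRUE, n, n)
  lt_any <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(objs))) {
    le_all <- le_all & outer(objs[, k], objs[, k], "<=")
    lt_any <- lt_any | outer(objs[, k], objs[, k], "<")
  }
  dom <- le_all & lt_any
  n_dom <- colSums(dom)               # how many dominate j
  fronts <- list()
  assigned <- logical(n)
  while (!all(assigned)) {
    current <- which(!assigned & n_dom == 0L)
    fronts[[length(fronts) + 1L]] <- current
    assigned[current] <- TRUE
    n_dom <- n_dom - colSums(dom[current, , drop = FALSE])
    n_dom[current] <- 1L              # keep them out of later fronts
  }
  fronts
}

#' Crowding distance within one front
#'
#' Boundary individuals on each objective receive `Inf`; interior ones the
#' sum of normalised neighbour gaps. A zero objective range contributes 0.
#'
#' @param objs Numeric matrix of the front members' objectives.
#' @return Numeric vector of distances.
#' @export
crowding_distance <- function(objs) {
  m <- nrow(objs)
  if (m <= 2) return(rep(Inf, m))
  d <- numeric(m)
  for (k in seq_len(ncol(objs))) {
    ord <- order(objs[, k])            # stable for ties
    rng <- objs[ord[m], k] - objs[ord[1], k]
    d[ord[1]] <- Inf
    d[ord[m]] <- Inf
    if (rng > 0) {
      for (i in 2:(m - 1)) {
        d[ord[i]] <- d[ord[i]] + (objs[ord[i + 1], k] - objs[ord[i - 1], k]) / rng
      }
    }
  }
  d
}

# --- internal GA machinery -------------------------------------------------

new_individual <- function(tree, X, labels, threshold) {
  obj <- objectives(tree, X, labels, threshold)
  list(tree = tree, objectives = obj, rank = NA_integer_,
       crowding = NA_real_, nodes = tree_size(tree))
}

obj_matrix <- function(pop) {
  t(vapply(pop, function(ind) ind$objectives, numeric(2)))
}

# binary (or k-ary) tournament: on (rank asc, crowding desc) in
# multi-objective mode, on raw BCE in the single-objective baseline
tournament_pick <- function(pop, k, mode = "multi") {
  cand <- sample.int(length(pop), k, replace = TRUE)
  best <- cand[1]
  for (c in cand[-1]) {
    if (mode == "bce") {
      if (pop[[c]]$objectives[1] < pop[[best]]$objectives[1]) best <- c
    } else if (pop[[c]]$rank < pop[[best]]$rank ||
        (pop[[c]]$rank == pop[[best]]$rank &&
         pop[[c]]$crowding > pop[[best]]$crowding)) best <- c
  }
  pop[[best]]
}

subtree_crossover <- function(t1, t2, max_depth) {
  p1 <- node_paths(t1); p2 <- node_paths(t2)
  a <- p1[[sample.int(length(p1), 1)]]
  b <- p2[[sample.int(length(p2), 1)]]
  child <- set_node(t1, a, get_node(t2, b))
  if (tree_depth(child) > max_depth) t1 else child
}

mutate_tree <- function(tree, features, max_depth, const_range,
                        ops = operator_set()) {
  paths <- node_paths(tree)
  path <- paths[[sample.int(length(paths), 1)]]
  if (stats::runif(1) < 0.5) {
    # subtree mutation: replace with a fresh grown subtree
    sub <- random_tree(features, max_depth = 3, method = "grow",
                       const_range = const_range, ops = ops)
    child <- set_node(tree, path, sub)
    if (tree_depth(child) > max_depth) tree else child
  } else {
    # point mutation: same-arity operator swap or terminal refresh
    node <- get_node(tree, path)
    if (!is_leaf(node)) {
      arity <- ops[[node$op]]$arity
      same <- names(ops)[vapply(ops, function(o) o$arity, integer(1)) == arity]
      node$op <- sample(same, 1)
    } else if (!is.null(node$const)) {
      node <- const_node(node$const + stats::rnorm(1, 0, 0.5))
    } else if (length(features)) {
      node <- feat_node(sample(features, 1))
    }
    set_node(tree, path, node)
  }
}

# ramped half-and-half initial population
init_population <- function(params, features, X, labels) {
  depths <- rep(seq(params$init_depth[1], params$init_depth[2]),
                length.out = params$population)
  lapply(seq_len(params$population), function(i) {
    method <- if (i %% 2 == 0) "full" else "grow"
    tree <- random_tree(features, max_depth = depths[i], method = method,
                        const_range = params$const_range)
    new_individual(tree, X, labels, params$threshold)
  })
}

# assign ranks and crowding to a population in place
assign_rank_crowding <- function(pop) {
  objs <- obj_matrix(pop)
  fronts <- non_dominated_sort(objs)
  for (r in seq_along(fronts)) {
    idx <- fronts[[r]]
    cd <- crowding_distance(objs[idx, , drop = FALSE])
    for (k in seq_along(idx)) {
      pop[[idx[k]]]$rank <- r - 1L
      pop[[idx[k]]]$crowding <- cd[k]
    }
  }
  pop
}

# elitist mu+lambda environmental selection by (rank, crowding), with an
# explicit guarantee that the per-objective best individuals survive (this
# makes per-generation best-objective traces exactly monotone)
environmental_selection <- function(combined, mu) {
  objs <- obj_matrix(combined)
  fronts <- non_dominated_sort(objs)
  chosen <- integer(0)
  for (f in fronts) {
    cd <- crowding_distance(objs[f, , drop = FALSE])
    if (length(chosen) + length(f) <= mu) {
      chosen <- c(chosen, f[order(-cd)])
    } else {
      need <- mu - length(chosen)
      chosen <- c(chosen, f[order(-cd)][seq_len(need)])
      break
    }
  }
  replace_pos <- length(chosen)
  protected <- integer(0)
  for (k in seq_len(ncol(objs))) {
    best <- which.min(objs[, k])
    if (!best %in% chosen) {
      while (replace_pos > 1 && chosen[replace_pos] %in% protected)
        replace_pos <- replace_pos - 1L
      chosen[replace_pos] <- best
      replace_pos <- replace_pos - 1L
    }
    protected <- c(protected, best)
  }
  assign_rank_crowding(combined[chosen])
}

# single-objective (BCE) generational step used by the baseline mode
bce_selection <- function(combined, mu) {
  objs <- obj_matrix(combined)
  keep <- order(objs[, 1])[seq_len(mu)]
  pop <- combined[keep]
  for (i in seq_along(pop)) { pop[[i]]$rank <- 0L; pop[[i]]$crowding <- Inf }
  pop
}

#' Evolve a population of symbolic-regression classifiers
#'
#' Generational loop: ramped half-and-half initialisation, objective
#' evaluation, binary tournament on (dominance rank, crowding distance),
#' subtree crossover and subtree/point mutation, then elitist mu+lambda
#' survival of the best `population` individuals from parents plus
#' offspring. Returns the final non-dominated front (deduplicated by
#' serialized formula) and a per-generation history of the best value of
#' each objective.
#'
#' @param X Numeric feature matrix (or `feature_matrix`) without missing
#'   entries.
#' @param labels 0/1 outcome vector, both classes present.
#' @param params [evolution_params()].
#' @return list of class `mosr_fit`: `front` (list of individuals),
#'   `population`, `history` (data.frame generation / best_bce / best_f1c /
#'   front_size), `params`, `features`.
#' @export
evolve <- function(X, labels, params = evolution_params()) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (anyNA(X)) stop("feature matrix must be complete")
  features <- colnames(X)
  mu <- params$population

  pop <- with_seed(substream_seed(params$seed, "init"),
                   init_population(params, features, X, labels))
  pop <- assign_rank_crowding(pop)

  history <- data.frame(generation = integer(0), best_bce = numeric(0),
                        best_f1c = numeric(0), front_size = integer(0))
  gen_seed <- substream_seed(params$seed, "generations")

  for (gen in seq_len(params$generations)) {
    offspring <- with_seed(gen_seed + gen, {
      lapply(seq_len(mu), function(i) {
        p1 <- tournament_pick(pop, params$tournament, params$objective)
        child <- if (stats::runif(1) < params$p_crossover) {
          p2 <- tournament_pick(pop, params$tournament, params$objective)
          subtree_crossover(p1$tree, p2$tree, params$max_depth)
        } else p1$tree
        if (stats::runif(1) < params$p_mutation)
          child <- mutate_tree(child, features, params$max_depth,
                               params$const_range)
        child
      })
    })
    offspring <- lapply(offspring, function(tr)
      new_individual(tr, X, labels, params$threshold))
    combined <- c(pop, offspring)
    pop <- if (params$objective == "bce") bce_selection(combined, mu)
           else environmental_selection(combined, mu)
    objs <- obj_matrix(pop)
    history <- rbind(history, data.frame(
      generation = gen,
      best_bce = min(objs[, 1]),
      best_f1c = min(objs[, 2]),
      front_size = sum(vapply(pop, function(i) i$rank == 0L, logical(1)))))
  }

  front <- pop[vapply(pop, function(i) i$rank == 0L, logical(1))]
  keys <- vapply(front, function(i) serialize_formula(i$tree), character(1))
  front <- front[!duplicated(keys)]
  structure(list(front = front, population = pop, history = history,
                 params = params, features = features),
            class = "mosr_fit")
}

#' @export
print.mosr_fit <- function(x, ...) {
  cat(sprintf("<mosr_fit> %d generations, front of %d model(s)\n",
              nrow(x$history), length(x$front)))
  if (nrow(x$history))
    cat(sprintf("  final best BCE %.4f, best F1 %.4f\n",
                x$history$best_bce[nrow(x$history)],
                1 - x$history$best_f1c[nrow(x$history)]))
  invisible(x)
}

#' Select the final model from a Pareto front
#'
#' Ranks front members by (AUC, sensitivity, specificity) on the supplied
#' data, descending lexicographically; full ties go to the smaller tree,
#' then to serialized-formula order.
#'
#' @param front List of individuals (e.g. `fit$front`).
#' @param X Evaluation feature matrix.
#' @param labels 0/1 outcome vector.
#' @param threshold Classification threshold.
#' @return list: `individual` (the winner), `table` (per-member metrics).
#' @export
select_final_model <- function(front, X, labels, threshold = 0.5) {
  if (!length(front)) stop("empty front")
  rows <- lapply(front, function(ind) {
    p <- predict_probability(ind$tree, X)
    cts <- confusion(labels, p, threshold)
    pan <- metric_panel(cts)
    data.frame(formula = serialize_formula(ind$tree),
               auc = roc_auc(labels, p),
               sensitivity = ifelse(is.na(pan$sensitivity), -Inf, pan$sensitivity),
               specificity = ifelse(is.na(pan$specificity), -Inf, pan$specificity),
               f1 = ifelse(is.na(pan$f1), -Inf, pan$f1),
               nodes = ind$nodes, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$auc, -tab$sensitivity, -tab$specificity,
               tab$nodes, tab$formula)
  list(individual = front[[ord[1]]], table = tab[ord, , drop = FALSE])
}

#' Write / read a model file
#'
#' Plain text: first line the serialized formula, second line a JSON
#' metadata object (objectives, seed, parameter summary).
#'
#' @param individual A front member (list with `tree`, `objectives`).
#' @param path File path.
#' @param params Optional [evolution_params()] stored in the metadata.
#' @return `read_model` returns list(tree, meta).
#' @export
write_model <- function(individual, path, params = NULL) {
  meta <- list(objectives = as.list(individual$objectives),
               nodes = individual$nodes,
               seed = if (!is.null(params)) params$seed else NULL,
               population = if (!is.null(params)) params$population else NULL,
               generations = if (!is.null(params)) params$generations else NULL)
  writeLines(c(serialize_formula(individual$tree),
               as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA, null = "null"))),
             path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  list(tree = parse_formula(lines[1]),
       meta = if (length(lines) > 1) jsonlite::fromJSON(lines[2]) else NULL)
}
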