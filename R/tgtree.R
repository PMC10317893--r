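# Conditional inference tree for a binary endpoint.
#
# Recursive partitioning in the permutation-test framework: at each node a
# Bonferroni-adjusted association test selects the splitting variable (or
# stops), then an exhaustive standardized two-sample scan selects the
# cutpoint. Stopping is significance-based (no pruning). Node numbering is
# depth-first preorder.

#' Fit a conditional inference tree for a binary endpoint
#'
#' At each node, every candidate predictor is tested for association with
#' the endpoint by a permutation-framework linear statistic
#' ([association_test()]); the minimum p-value is Bonferroni-adjusted over
#' the number of predictors tested and the node is split only if the
#' adjusted p-value is at most `alpha`. The split point for the selected
#' predictor maximizes the standardized two-sample statistic over all
#' admissible cutpoints ([find_cutpoint()]). Records with value `<=`
#' cutpoint (or level in the reported subset) go left.
#'
#' @param formula Model formula; the response may be the `ptwbs` factor
#'   (binarized via [binarize_endpoint()]) or a 0/1 vector. `.` expands to
#'   the canonical nine predictors present in `data` (never `center`).
#' @param data A data.frame or `tg_cohort`.
#' @param weights Optional non-negative case weights.
#' @param alpha Significance level for the adjusted test (default 0.05).
#' @param minsplit Minimum node weight to attempt a split (default 20).
#' @param minbucket Minimum child weight (default 7).
#' @param maxdepth Maximum depth (root = depth 0; default unlimited).
#' @return An object of class `"tgtree"` with components `root` (nested
#'   node list), `params`, `predictors`, `nobs`, `call`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 400), seed = 1)
#' fit <- tgtree(ptwbs ~ tg + n_stage, data = coh)
#' print(fit)
#' predict(fit, coh[1:3, ], type = "risk")
#' @export
tgtree <- function(formula, data, weights = NULL, alpha = 0.05,
                   minsplit = 20L, minbucket = 7L, maxdepth = Inf) {
  stopifnot(alpha > 0, alpha < 1, minbucket >= 1, minsplit >= 2 * minbucket)
  data <- as.data.frame(data)
  # `.` on the rhs: canonical predictors only (center stays passive)
  tf <- stats::terms(formula, data = data[setdiff(names(data), "center")])
  resp_name <- all.vars(formula[[2]])
  vars <- attr(tf, "term.labels")
  vars <- intersect(vars, names(data))
  if (length(vars) == 0L) stop("no predictors in formula")
  yraw <- data[[resp_name]]
  if (is.null(yraw)) stop("response `", resp_name, "` not found")
  y <- if (is.numeric(yraw)) {
    if (!all(yraw %in% 0:1)) stop("numeric response must be 0/1")
    as.integer(yraw)
  } else binarize_endpoint(yraw)
  n <- length(y)
  if (n == 0L) stop("empty cohort")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0)) stop("invalid weights")
  if (anyNA(data[vars]) || anyNA(y)) stop("missing values are not supported; exclude incomplete records upstream")

  # canonical tie-break ordering of predictors
  vars <- vars[order(match(vars, tg_schema$predictors,
                           nomatch = length(vars) + 1L))]
  pd <- data[vars]
  id_counter <- new.env(); id_counter$i <- 0L

  grow <- function(idx, depth) {
    id_counter$i <- id_counter$i + 1L
    id <- id_counter$i
    wi <- w[idx]; yi <- y[idx]
    W <- sum(wi)
    risk <- sum(wi * yi) / W
    terminal <- list(id = id, terminal = TRUE, n = W, risk = risk)
    if (W < minsplit || risk %in% c(0, 1) || depth >= maxdepth) return(terminal)
    sel <- select_split_variable(pd[idx, , drop = FALSE], yi, wi, alpha = alpha)
    if (is.null(sel)) return(terminal)
    x <- pd[idx, sel$variable]
    cp <- find_cutpoint(x, yi, wi, minbucket = minbucket)
    if (is.null(cp)) return(terminal)
    left_mask <- if (!is.null(cp$levels)) x %in% cp$levels
    else (if (is.ordered(x)) as.numeric(x) else x) <= cp$cutpoint
    if (sum(wi[left_mask]) < minbucket || sum(wi[!left_mask]) < minbucket) {
      return(terminal)  # defensive; find_cutpoint enforces admissibility
    }
    node <- list(id = id, terminal = FALSE, n = W,
                 predictor = sel$variable, p_adj = sel$p_adj,
                 statistic = cp$statistic)
    if (!is.null(cp$levels)) node$levels <- cp$levels
    else {
      node$cutpoint <- cp$cutpoint
      if (!is.null(cp$cut_label)) node$cut_label <- cp$cut_label
    }
    node$left <- grow(idx[left_mask], depth + 1L)
    node$right <- grow(idx[!left_mask], depth + 1L)
    node
  }

  root <- grow(seq_len(n), 0L)
  structure(list(root = root,
                 params = list(alpha = alpha, minsplit = minsplit,
                               minbucket = minbucket, maxdepth = maxdepth),
                 predictors = vars,
                 response = resp_name,
                 nobs = sum(w),
                 provenance = attr(data, "provenance"),
                 call = match.call()),
            class = "tgtree")
}

#' Predict from a fitted tree
#'
#' Deterministic routing by "value <= cutpoint goes left". The predicted
#' class is positive iff the terminal risk exceeds 0.5; a terminal whose
#' risk is not available (see [published_model()]) classifies by its
#' recorded class.
#'
#' @param object A `tgtree`.
#' @param newdata data.frame of records carrying every predictor the tree
#'   uses.
#' @param type `"risk"` (event probability), `"class"` (0/1),
#'   `"node"` (terminal id) or `"all"` (data.frame of the three).
#' @param na_risk Optional numeric substitute returned as the risk score of
#'   risk-unavailable terminals (used when a downstream consumer, e.g. an
#'   AUC, needs a complete score vector); the predicted class is unaffected.
#' @param ... Unused.
#' @return A vector, or data.frame for `type = "all"`.
#' @export
predict.tgtree <- function(object, newdata,
                           type = c("risk", "class", "node", "all"),
                           na_risk = NULL, ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  risk <- numeric(n); nodeid <- integer(n); cls <- integer(n)
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$terminal) {
      nodeid[idx] <<- node$id
      risk[idx] <<- node$risk
      cls[idx] <<- if (is.na(node$risk)) {
        as.integer(identical(node$class, "positive"))
      } else as.integer(node$risk > 0.5)
      return(invisible())
    }
    x <- newdata[[node$predictor]]
    if (is.null(x)) stop("missing predictor value: ", node$predictor)
    x <- x[idx]
    if (anyNA(x)) stop("missing predictor value: ", node$predictor)
    go_left <- if (!is.null(node$levels)) as.character(x) %in% node$levels
    else (if (is.ordered(x)) as.numeric(x) else as.numeric(x)) <= node$cutpoint
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(object$root, seq_len(n))
  if (!is.null(na_risk)) risk[is.na(risk)] <- na_risk
  switch(type,
         risk = risk, class = cls, node = nodeid,
         all = data.frame(node = nodeid, risk = risk, class = cls))
}

# apply f to every node (preorder); collect results in a list
.walk <- function(node, f) {
  out <- list(f(node))
  if (!node$terminal) {
    out <- c(out, .walk(node$left, f), .walk(node$right, f))
  }
  out
}

#' Terminal nodes of a fitted tree
#'
#' @param tree A `tgtree`.
#' @return data.frame with one row per terminal: `id`, `n`, `risk`.
#' @export
terminal_nodes <- function(tree) {
  terms <- Filter(function(nd) nd$terminal, .walk(tree$root, identity))
  data.frame(id = vapply(terms, `[[`, integer(1), "id"),
             n = vapply(terms, `[[`, numeric(1), "n"),
             risk = vapply(terms, function(t) as.numeric(t$risk), numeric(1)))
}

# inner-node split descriptions
inner_nodes <- function(tree) {
  inner <- Filter(function(nd) !nd$terminal, .walk(tree$root, identity))
  data.frame(
    id = vapply(inner, `[[`, integer(1), "id"),
    predictor = vapply(inner, `[[`, character(1), "predictor"),
    cutpoint = vapply(inner, function(nd)
      if (is.null(nd$cutpoint)) NA_real_ else as.numeric(nd$cutpoint), numeric(1)),
    p_adj = vapply(inner, function(nd)
      if (is.null(nd$p_adj)) NA_real_ else nd$p_adj, numeric(1))
  )
}

#' Variables used by a fitted tree
#'
#' @param tree A `tgtree`.
#' @return Character vector of predictors appearing in at least one inner
#'   node (empty for a root-only tree).
#' @export
tree_variables <- function(tree) {
  if (tree$root$terminal) return(character(0))
  unique(inner_nodes(tree)$predictor)
}

.fmt_split <- function(node, side) {
  if (!is.null(node$levels)) {
    lv <- if (side == "left") node$levels else paste0("not{", paste(node$levels, collapse = ","), "}")
    if (side == "left") paste0(node$predictor, " in {", paste(lv, collapse = ","), "}")
    else paste0(node$predictor, " ", lv)
  } else {
    cut <- if (!is.null(node$cut_label)) node$cut_label else signif(node$cutpoint, 6)
    paste0(node$predictor, if (side == "left") " <= " else " > ", cut)
  }
}

.print_node <- function(node, indent = "") {
  if (node$terminal) {
    cat(sprintf("%s* terminal [%d]: n = %g, risk = %s\n", indent, node$id,
                node$n, if (is.na(node$risk)) "not reported"
                else sprintf("%.3f", node$risk)))
  } else {
    cat(sprintf("%s[%d] %s  (p_adj = %s, n = %g)\n", indent, node$id,
                .fmt_split(node, "left"),
                if (is.null(node$p_adj) || is.na(node$p_adj)) "-"
                else format.pval(node$p_adj, digits = 3), node$n))
    .print_node(node$left, paste0(indent, "|   "))
    cat(sprintf("%s[%d] %s\n", indent, node$id, .fmt_split(node, "right")))
    .print_node(node$right, paste0(indent, "|   "))
  }
}

#' @export
print.tgtree <- function(x, ...) {
  cat("Conditional inference tree (binary endpoint)\n")
  cat(sprintf("  n = %g, predictors: %s\n", x$nobs,
              paste(x$predictors, collapse = ", ")))
  .print_node(x$root)
  invisible(x)
}

#' @export
summary.tgtree <- function(object, ...) {
  tn <- terminal_nodes(object)
  structure(list(params = object$params,
                 predictors = object$predictors,
                 used = tree_variables(object),
                 terminals = tn,
                 splits = if (object$root$terminal) NULL else inner_nodes(object),
                 nobs = object$nobs),
            class = "summary.tgtree")
}

#' @export
print.summary.tgtree <- function(x, ...) {
  cat(sprintf("tgtree fit: n = %g, %d terminal node(s)\n",
              x$nobs, nrow(x$terminals)))
  cat("  predictors offered:", paste(x$predictors, collapse = ", "), "\n")
  cat("  predictors used:   ",
      if (length(x$used)) paste(x$used, collapse = ", ") else "(none)", "\n")
  cat("  terminal risks:\n")
  print(x$terminals, row.names = FALSE)
  invisible(x)
}

#' Serialize a fitted tree to JSON
#'
#' Nodes serialize as nested objects: inner nodes carry `predictor`,
#' `cutpoint` or `level_subset`, `p_adj` and `children`; terminals carry
#' `n` and `risk`. The document is stable across platforms.
#'
#' @param tree A `tgtree`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  ser <- function(node) {
    if (node$terminal) {
      out <- list(n = node$n, risk = node$risk)
      if (!is.null(node$class)) out$class <- node$class
      return(out)
    }
    out <- list(predictor = node$predictor)
    if (!is.null(node$levels)) out$level_subset <- as.list(node$levels)
    else out$cutpoint <- node$cutpoint
    if (!is.null(node$p_adj)) out$p_adj <- node$p_adj
    out$children <- list(ser(node$left), ser(node$right))
    out
  }
  doc <- list(model = "tgtree", params = tree$params,
              predictors = as.list(tree$predictors),
              root = ser(tree$root))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Deserialize a tree written by [tree_to_json()]
#'
#' @param path File path or a JSON string.
#' @return A `tgtree` object.
#' @export
tree_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$model, "tgtree")) stop("not a tgtree JSON document")
  id_counter <- new.env(); id_counter$i <- 0L
  de <- function(nd) {
    id_counter$i <- id_counter$i + 1L
    if (!is.null(nd$children)) {
      out <- list(id = id_counter$i, terminal = FALSE,
                  n = if (is.null(nd$n)) NA_real_ else nd$n,
                  predictor = nd$predictor,
                  p_adj = if (is.null(nd$p_adj)) NA_real_ else nd$p_adj)
      if (!is.null(nd$level_subset)) out$levels <- unlist(nd$level_subset)
      else out$cutpoint <- nd$cutpoint
      out$left <- de(nd$children[[1]])
      out$right <- de(nd$children[[2]])
      out
    } else {
      list(id = id_counter$i, terminal = TRUE,
           n = if (is.null(nd$n)) NA_real_ else nd$n,
           risk = if (is.null(nd$risk)) NA_real_ else nd$risk,
           class = nd$class)
    }
  }
  root <- de(doc$root)
  # recover per-inner-node n where missing
  structure(list(root = root, params = doc$params,
                 predictors = unlist(doc$predictors),
                 response = "ptwbs", nobs = root$n, call = NULL),
            class = "tgtree")
}
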