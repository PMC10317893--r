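# The published five-node decision tree as an executable risk calculator.

#' The published decision-tree risk calculator
#'
#' A fixed `tgtree` encoding the published five-terminal model: the root
#' splits on lymph-node stage; node-positive patients split on Tg at
#' 23.3 ng/mL (risk 83% above), node-negative patients split on Tg at
#' 35 ng/mL (56.3% above) and, below that, at 7.1 ng/mL (15.2% for
#' 7.1 < Tg <= 35 and 5.8% at or below 7.1). The N1, Tg <= 23.3 terminal
#' risk was not reported; it is carried as `NA` ("not reported") with
#' predicted class negative (the branch is only described as lower risk).
#'
#' Split boundaries are right-closed (`tg <= cutoff` goes to the lower
#' band), matching the fitting convention.
#'
#' @return A `tgtree` of class `c("tg_published_model", "tgtree")`.
#' @examples
#' m <- published_model()
#' predict(m, data.frame(n_stage = 1, tg = 30), type = "risk")   # 0.83
#' predict(m, data.frame(n_stage = 0, tg = 1), type = "risk")    # 0.058
#' @export
published_model <- function() {
  term <- function(id, risk, class = NULL) {
    nd <- list(id = id, terminal = TRUE, n = NA_real_, risk = risk)
    if (!is.null(class)) nd$class <- class
    nd
  }
  root <- list(
    id = 1L, terminal = FALSE, n = NA_real_, predictor = "n_stage",
    cutpoint = 0, p_adj = NA_real_,
    left = list(  # N0 branch
      id = 2L, terminal = FALSE, n = NA_real_, predictor = "tg",
      cutpoint = 35, p_adj = NA_real_,
      left = list(
        id = 3L, terminal = FALSE, n = NA_real_, predictor = "tg",
        cutpoint = 7.1, p_adj = NA_real_,
        left = term(4L, 0.058),
        right = term(5L, 0.152)
      ),
      right = term(6L, 0.563)
    ),
    right = list(  # N1 branch
      id = 7L, terminal = FALSE, n = NA_real_, predictor = "tg",
      cutpoint = 23.3, p_adj = NA_real_,
      left = term(8L, NA_real_, class = "negative"),
      right = term(9L, 0.83)
    )
  )
  structure(list(root = root,
                 params = list(alpha = 0.05, minsplit = 20L, minbucket = 7L,
                               maxdepth = Inf),
                 predictors = c("tg", "n_stage"),
                 response = "ptwbs",
                 nobs = NA_real_,
                 call = quote(published_model())),
            class = c("tg_published_model", "tgtree"))
}

#' Risk, path and class for records under a model
#'
#' Convenience wrapper around [predict.tgtree()] returning terminal id,
#' risk and the 0.5-threshold predicted class for each record (class
#' positive iff risk > 0.5; risk-unavailable terminals classify by their
#' recorded class).
#'
#' @param model A `tgtree` (fitted or [published_model()]).
#' @param records data.frame carrying the model's predictors.
#' @return data.frame with columns `node`, `risk`, `class`.
#' @export
predict_risk <- function(model, records) {
  predict(model, records, type = "all")
}
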