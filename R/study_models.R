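#' The three selected study models
#'
#' Returns the specification, published fitted coefficients and covariate
#' set of the three models selected for the gastric IM risk study:
#' \describe{
#'   \item{model1}{cumulative po with loglog/logit links, TNSC only
#'     (intercepts 4.023 and 4.905, TNSC slope -4.228e-4).}
#'   \item{model2}{adjacent-categories po with logit links, TNSC plus the
#'     5-class atrophy dummies (mild, moderate, negative, unknown; Marked
#'     baseline).}
#'   \item{model3}{adjacent-categories po with probit links, TNSC plus the
#'     3-class atrophy dummies (mild, moderate; Negative baseline), for the
#'     subset excluding Marked/Unknown atrophy.}
#' }
#'
#' @param name \code{"model1"}, \code{"model2"} or \code{"model3"}.
#' @return List with \code{spec} (\code{"mml_spec"}), \code{theta} (named
#'   coefficients in theta order) and \code{covariate_set}.
#' @examples
#' study_model("model1")$theta
#' @export
study_model <- function(name = c("model1", "model2", "model3")) {
  name <- match.arg(name)
  switch(name,
    model1 = list(
      spec = mixed_link_spec("cumulative", c("loglog", "logit"), "po",
                             d = 1L, covariate_names = "tnsc"),
      theta = c(beta0_1 = 4.023, beta0_2 = 4.905, tnsc = -4.228e-4),
      covariate_set = "tnsc"),
    model2 = list(
      spec = mixed_link_spec("adjacent", c("logit", "logit"), "po",
                             d = 5L,
                             covariate_names = c("tnsc", "mild", "moderate",
                                                 "negative", "unknown")),
      theta = c(beta0_1 = -1.859, beta0_2 = 0.136, tnsc = -4.586e-4,
                mild = -1.144, moderate = -2.103, negative = 6.469,
                unknown = 3.663),
      covariate_set = "tnsc_atrophy5"),
    model3 = list(
      spec = mixed_link_spec("adjacent", c("probit", "probit"), "po",
                             d = 3L,
                             covariate_names = c("tnsc", "mild", "moderate")),
      theta = c(beta0_1 = 3.153, beta0_2 = 5.275, tnsc = -3.446e-4,
                mild = -4.260, moderate = -5.347),
      covariate_set = "tnsc_atrophy3")
  )
}
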