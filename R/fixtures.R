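#' Bundled decision-matrix fixtures
#'
#' The package ships the decision matrix of a published fuzzy-PROMETHEE
#' evaluation of nine machine-learning brain-tumor classifiers (SVM, RF,
#' GBM, CNN, KNN, AlexNet, GoogLeNet, CNN VGG19, CapsNet) on six criteria:
#' average prediction accuracy, precision, recall, processing time in
#' seconds (the one min-aim criterion), sensitivity and specificity. Every
#' cell stores both the raw numeric value and the linguistic term exactly
#' as published — including the handful of cells whose printed term
#' contradicts the percentage banding rule; [validate_labels()] surfaces
#' those instead of hiding them.
#'
#' Available fixtures:
#'
#' * `brain_tumor_linguistic` — published terms and values, default weights
#'   `VH, VH, H, H, H, VH`. Analyse with `mode = "linguistic"`.
#' * `brain_tumor_raw` — the same matrix; analyse with `mode = "raw"` to
#'   use the numeric values directly.
#' * `brain_tumor_sensitivity` — same matrix with the specificity weight
#'   changed `VH -> M` (the study's sensitivity scenario).
#'
#' @param name Fixture name.
#' @return [load_fixture()] returns a [decision_matrix()];
#'   [list_fixtures()] a tibble of names and descriptions.
#' @examples
#' dm <- load_fixture("brain_tumor_linguistic")
#' print(dm)
#' @export
load_fixture <- function(name) {
  known <- list_fixtures()$name
  if (length(name) != 1L || !name %in% known) {
    abort_input(paste0("Unknown fixture '", paste(name, collapse = ", "),
                       "'. Available fixtures: ", paste(known, collapse = ", "), "."))
  }
  path <- system.file("extdata", "brain_tumor.csv", package = "fpromethee",
                      mustWork = TRUE)
  dm <- read_decision_csv(path)
  if (name == "brain_tumor_sensitivity") {
    dm <- set_weight(dm, "specificity", "M")
  }
  dm
}

#' @rdname load_fixture
#' @export
list_fixtures <- function() {
  tibble(
    name = c("brain_tumor_linguistic", "brain_tumor_raw", "brain_tumor_sensitivity"),
    description = c(
      "9 ML classifiers x 6 criteria, published linguistic terms, weights VH,VH,H,H,H,VH",
      "Same matrix, raw numeric values (use mode = 'raw')",
      "Same matrix with the specificity weight changed VH -> M"
    )
  )
}
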