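#' Build a dataset manifest from class folders
#'
#' Discovers images under `root/<Benign|Malignant|Normal>/`, in deterministic
#' lexicographic order. Files whose header bytes identify neither PNG nor JPEG
#' are reported with a warning and skipped.
#'
#' @param root directory containing the three class folders.
#' @return tibble with columns `path`, `label`, `split` (`"unsplit"`).
#' @export
build_manifest <- function(root) {
  assert_that(dir.exists(root), sprintf("dataset root not found: %s", root))
  missing <- LUNG_CLASSES[!dir.exists(file.path(root, LUNG_CLASSES))]
  assert_that(length(missing) == 0,
              sprintf("missing class folder(s): %s", paste(missing, collapse = ", ")))
  paths <- character(0); labels <- character(0)
  for (cl in LUNG_CLASSES) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                             full.names = TRUE))
    keep <- vapply(files, is_decodable_image, logical(1))
    if (any(!keep)) {
      warning(sprintf("skipping unreadable image(s): %s",
                      paste(files[!keep], collapse = ", ")), call. = FALSE)
    }
    files <- files[keep]
    assert_that(length(files) > 0, sprintf("class folder '%s' contains no readable images", cl))
    paths <- c(paths, files)
    labels <- c(labels, rep(cl, length(files)))
  }
  tibble::tibble(path = paths, label = labels, split = "unsplit")
}

# Cheap header check: PNG and JPEG magic bytes.
is_decodable_image <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 8)
  if (length(sig) < 3) return(FALSE)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47))
  jpg_sig <- as.raw(c(0xff, 0xd8, 0xff))
  identical(sig[1:4], png_sig) || identical(sig[1:3], jpg_sig)
}

#' Per-class record counts of a manifest
#' @param manifest a manifest tibble.
#' @return named integer vector over the three classes.
#' @export
manifest_counts <- function(manifest) {
  vapply(LUNG_CLASSES, function(cl) sum(manifest$label == cl), integer(1))
}

#' Balanced train/test split
#'
#' Samples exactly `test_per_class` records per class, without replacement,
#' with the given seed; the remainder forms the training set. The two parts
#' are an exact partition of the input. With the reference class sizes
#' 530/536/534 and the default 150 per class this yields a 450-image balanced
#' test set and a 1,150-image training set (380/386/384).
#'
#' @param manifest a manifest tibble.
#' @param test_per_class held-out records per class (default 150).
#' @param seed RNG seed for the sampling.
#' @return list with tibbles `train` and `test` (with `split` set).
#' @export
split_manifest <- function(manifest, test_per_class = 150L, seed = 42L) {
  counts <- manifest_counts(manifest)
  short <- names(counts)[counts < test_per_class]
  assert_that(length(short) == 0,
              sprintf("class(es) with fewer than %d records: %s",
                      test_per_class, paste(short, collapse = ", ")))
  test_idx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cl in LUNG_CLASSES) {
      idx <- which(manifest$label == cl)
      test_idx <- c(test_idx, sample(idx, test_per_class))
    }
  })
  test_idx <- sort(test_idx)
  train <- manifest[-test_idx, , drop = FALSE]
  test <- manifest[test_idx, , drop = FALSE]
  if (nrow(train) == 0) warning("training split is empty", call. = FALSE)
  train$split <- "train"
  test$split <- "test"
  list(train = train, test = test)
}

#' One-hot encode class labels
#'
#' Fixed column order Benign = 1, Malignant = 2, Normal = 3; every row sums
#' to exactly 1 (categorical cross-entropy targets).
#'
#' @param labels character vector of class labels.
#' @return numeric matrix `length(labels)` x 3.
#' @export
encode_labels <- function(labels) {
  unknown <- setdiff(unique(labels), LUNG_CLASSES)
  assert_that(length(unknown) == 0,
              sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
  m <- matrix(0, length(labels), 3, dimnames = list(NULL, LUNG_CLASSES))
  m[cbind(seq_along(labels), match(labels, LUNG_CLASSES))] <- 1
  m
}

#' Read / write a manifest CSV (`path,label,split`)
#' @param manifest a manifest tibble.
#' @param path CSV file path.
#' @return the manifest (invisibly for the writer).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("path", "label", "split") %in% names(df)),
              "manifest CSV must have columns path,label,split")
  tibble::as_tibble(df)
}
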