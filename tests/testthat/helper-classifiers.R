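# Classifiers shared across test files. Training the compact CNN takes a
# couple of minutes, so each head is trained once per test run and cached.
# The binary head uses the package defaults on the n = 200 shapes dataset --
# the same conditions the segmentation benchmark is run under.

.otomifTestCache <- new.env(parent = emptyenv())

sharedBinaryData <- function() {
  if (is.null(.otomifTestCache$binData))
    .otomifTestCache$binData <- generateShapesDataset(200, seed = 5)
  .otomifTestCache$binData
}

sharedBinaryClassifier <- function() {
  if (is.null(.otomifTestCache$bin))
    .otomifTestCache$bin <- trainViewClassifier(sharedBinaryData(), seed = 1)
  .otomifTestCache$bin
}

sharedViewClassifier <- function() {
  if (is.null(.otomifTestCache$view)) {
    ds <- generateShapesDataset(200, seed = 11, classes = "view")
    .otomifTestCache$view <- trainViewClassifier(ds, epochs = 60, seed = 7)
  }
  .otomifTestCache$view
}

trainingAccuracy <- function(classifier, dataset) {
  pred <- vapply(dataset@images, function(im)
    names(which.max(predictProbs(classifier, im))), character(1))
  mean(pred == as.character(classLabels(dataset)))
}
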