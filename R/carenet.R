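#' Load the bundled CARENET cambium-regulation network
#'
#' CARENET models hormonal control of cambium proliferation as a 30-node
#' signed-threshold Boolean network: 6 control nodes for the external
#' hormonal/peptidic inputs (CK0 cytokinin, IAA0 auxin, BR brassinosteroids,
#' GA gibberellin, TDIF signalling peptide, ETHL ethylene) and 24 internal
#' nodes covering the cytokinin, auxin, ethylene, brassinosteroid and
#' TDIF/PXY signalling blocks. WOX4 and HB8 (ATHB8) serve as proliferation
#' reporters.
#'
#' The bundled edge list is a provisional transcription from the prose
#' description of the network blocks (see comments in the data file); it is
#' shipped as data so the wiring can be refined without code changes.
#'
#' @return A validated `boolean_network` with 30 nodes (6 control,
#'   24 internal).
#' @examples
#' net <- load_carenet()
#' net$N
#' control_nodes(net)
#' @export
load_carenet <- function() {
  path <- system.file("extdata", "carenet.net", package = "carenet",
                      mustWork = TRUE)
  read_network(path)
}
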