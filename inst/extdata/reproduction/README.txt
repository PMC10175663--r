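Reproduction kit for the published full-size evaluations.

The full-size runs require peptide-HLA structures modelled externally
(e.g. APE-Gen or DockTope / CrossTope) which cannot be redistributed with
the package. To reproduce:

1. Model or download one PDB per peptide (HLA heavy chain + bound
   peptide) and place them under a directory, e.g. structures/.
2. Fill in manifest_template.csv (one row per peptide; label TRUE for
   peptides recognised by the shared T-cell clone, FALSE for decoys).
3. Run, with the per-dataset settings from run_parameters.csv:

   Rscript inst/cli/pepsim.R run --manifest manifest.csv \
       --target <peptide> --linkage <ward|average> --out outdir

   or equivalently pepsim_run("manifest.csv", target = ...,
   linkage = ...) from R. All geometric parameters in
   run_parameters.csv are the package defaults, so only the linkage and
   clustering mode vary per dataset.
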