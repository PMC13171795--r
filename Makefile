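# Convenience targets; everything assumes the package is installed.

.PHONY: install test acceptance paper-suite

install:
	R CMD INSTALL --no-docs --no-html --no-help .

test:
	Rscript -e 'testthat::test_dir("tests/testthat", package = "picnet", load_package = "installed")'

acceptance:
	Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json

# grid search over the controller gains plus the three ablation suites on
# the shared synthetic dataset (64x64, one CPU, < 30 minutes)
paper-suite:
	Rscript scripts/paper_suite.R --seed 1 --out results/paper_suite
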