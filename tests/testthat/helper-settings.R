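# Keep generator/pipeline logging quiet during tests.
options(pdfftexture.log_level = "error")
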