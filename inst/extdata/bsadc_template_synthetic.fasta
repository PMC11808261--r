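>bsadc_template_synthetic synthetic stand-in for the BsADC pro-protein (anchor residues placed per published regions; remainder arbitrary)
MYRTMMSGKLHRATVTEADLNYVGSITIDQDLLDAAGILENEKVAIVNVNNGARLETYVIAGKERGSGVICLNGAAARLVQPGDLVWIMSYAQLDEKAAEVHPSVEKLNDDNKIVEMLGNEPASTIS
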