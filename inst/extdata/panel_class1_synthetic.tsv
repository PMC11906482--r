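# SYNTHETIC placeholder pseudo-sequences for 20 common HLA class-I alleles.
# Randomly generated stand-ins so the pipeline runs offline; replace with
# real contact-residue pseudo-sequences for production use.
allele	pseudo_sequence
HLA-A*01:01	SICTWGFPFWPQNMYGPFEMFVWRTNVFLMGECT
HLA-A*02:01	VMWHTVNVPNLKYTDCHFHPQNCPWMTHPCTDYV
HLA-A*03:01	GGLEANAREISPAATRAAIVNPLDCCGNVGLTWL
HLA-A*11:01	NFSQCLPTNLSRIYPWCNRSRAPNPWMADNEELI
HLA-A*23:01	FSFSPLHKICQMLQGFSEMVHFHVPTTFGGVMSQ
HLA-A*24:02	ANYKCLLANHNYLDYDDATTDPYYSNCVSYDIFW
HLA-A*26:01	MNEWCENWRGHCARNHKHYCYKDLYSMCGYRFMV
HLA-A*29:02	LDDIQEKQLACWVPETSMIFFSMYCFSKFKLSEI
HLA-A*68:01	QAMVDFNCVMSFLQSDLYQLKAFFSVALTHEHSA
HLA-B*07:02	IHPHEMVFFAEEVAMCDWWNQFEPYILIVTHDMP
HLA-B*08:01	LPSITVKLGPSPEWGFHFNESNVKCGPWSAAMPA
HLA-B*15:01	LIVIHNIRYEIKIAATGMSLKQAGAPMYTVSETC
HLA-B*18:01	PDMVRIDKDVYRNRTTQIKEFLWNRQLWFPCDFT
HLA-B*27:05	NPLPPLLPAFEMCTIPHQYFNSPQLFYGKQVSIG
HLA-B*35:01	GEAFSEECTIDHFMNKHACVFHQYNLCYPSIWCL
HLA-B*40:01	PYIEPWRDFFTKWPFIEAVIKKCDSSYSSGNLIE
HLA-B*44:02	NAYTMPRMASDFNRMIYGIQQCASWGLFRRGHHD
HLA-B*51:01	WMIHMPNEHYSRYQHTGHTTPDICWAGNFSECAI
HLA-C*04:01	SHPMTIAKMRAGIPQQGSSVPVQRELDHAATWPI
HLA-C*07:01	LSQGNSEAYEMFNEQDTWNCGELWIDCSVILRSL
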