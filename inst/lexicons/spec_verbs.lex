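# Speculative verbs for SpecVObj2+WN.  Entries without a key are seed
# verbs; entries with seed=<pred> are WordNet sisters (lemmas sharing a
# direct hypernym with a seed), expanded offline so no lexical database is
# consulted at run time.  The seed set is a reconstruction: only _test_v
# and _investigate_v are attested examples of the original six.
_test_v
_investigate_v
_examine_v
_study_v
_analyze_v
_assess_v
_probe_v	seed=_investigate_v
_explore_v	seed=_investigate_v
_inspect_v	seed=_examine_v
_scrutinize_v	seed=_examine_v
_evaluate_v	seed=_assess_v
_appraise_v	seed=_assess_v
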