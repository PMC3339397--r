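# Negative conjunctions for NegConjIndex, with the role(s) holding the
# negated daughter(s).  "nor" negates both conjuncts, so both index roles
# are listed; "not"/"but not" negate only the right conjunct.
_nor_c	daughters=L-INDEX,R-INDEX
_not_c	daughters=R-INDEX
_but+not_c	daughters=R-INDEX
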