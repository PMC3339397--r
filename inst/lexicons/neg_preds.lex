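# Semantically negative predicates consulted by NegOutscope2 and
# Arg0NegOutscopeeSA.  This set is a reconstruction: only _unable_a and
# _never_a are attested examples of the original nine; the rest (including
# neg_rel, the grammar's predicate for "not") were chosen as the predicates
# a precision grammar emits for common clausal and phrasal negators.
# Override by pointing read_lexicons() at your own directory.
neg_rel
_unable_a
_never_a
_no_q
_not+entirely_a
_fail_v
_lack_v
_absence_n
_without_p
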