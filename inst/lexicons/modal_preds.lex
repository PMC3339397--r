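# Modal predicates for ModalOutscope (reconstruction; the attested example
# is "should").
_can_v_modal
_could_v_modal
_may_v_modal
_might_v_modal
_must_v_modal
_should_v_modal
_would_v_modal
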