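sample_id	group
R01	responder
R02	responder
R03	responder
R04	responder
R05	responder
R06	responder
N01	non_responder
N02	non_responder
N03	non_responder
N04	non_responder
N05	non_responder
N06	non_responder
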