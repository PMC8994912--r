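episode_type,complication_class,n,men_n,men_pct_printed
incident,foot_disorder,1094,636,58.1
incident,nephropathy,371,236,63.6
incident,cardiovascular,1870,1056,56.5
incident,cerebrovascular,1367,699,51.1
incident,neurological,220,129,58.6
incident,eye,855,404,47.3
recurrent,nephropathy,625,427,68.3
recurrent,foot_disorder,1172,806,68.8
recurrent,cardiovascular,5355,3070,57.3
recurrent,neurological,136,75,55.1
recurrent,cerebrovascular,855,490,57.3
recurrent,eye,2228,1163,52.2
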