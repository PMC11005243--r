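# Default clinical response annotation mapping.
# Complete / partial response map to "response"; progressive disease,
# stable disease and the various non-response spellings map to
# "non-response".  Annotations are matched case-insensitively after
# whitespace normalization.  Supply your own file to override.
annotation	label
complete response	response
partial response	response
cr	response
pr	response
response	response
responder	response
nonresponse	non-response
non-response	non-response
no response	non-response
nonresponder	non-response
non-responder	non-response
progressive disease	non-response
pd	non-response
stable disease	non-response
sd	non-response
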