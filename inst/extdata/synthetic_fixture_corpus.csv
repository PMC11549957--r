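"report_id","category","text"
"cat1_r0001","cat1","tok0019 tok0034 tok0003 tok0001 tok0001 tok0003 tok0003 tok0001 tok0028 tok0003. tok0029 tok0054 tok0001 tok0054 tok0003 tok0003 tok0002 tok0042 tok0003. tok0003 tok0001 tok0002 tok0027 tok0002 tok0001 tok0029 tok0003 tok0001."
"cat1_r0002","cat1","tok0001 tok0020 tok0022."
"cat1_r0003","cat1","tok0002 tok0003 tok0015 tok0001 tok0002. tok0013 tok0002 tok0002 tok0002 tok0052 tok0036 tok0045 tok0001."
"cat1_r0004","cat1","tok0003 tok0041 tok0043 tok0032 tok0024. tok0001 tok0049 tok0050 tok0060 tok0055."
"cat1_r0005","cat1","tok0045 tok0003 tok0002 tok0002 tok0001. tok0001 tok0032 tok0026 tok0002 tok0030 tok0001 tok0023 tok0003. tok0030 tok0001 tok0012 tok0002 tok0003 tok0005. tok0002 tok0001 tok0001 tok0002 tok0042 tok0056. tok0004 tok0001 tok0019 tok0015 tok0003 tok0003 tok0002."
"cat1_r0006","cat1","tok0002 tok0035 tok0003 tok0047 tok0001 tok0028 tok0002 tok0037. tok0001 tok0032 tok0002 tok0003 tok0007 tok0002. tok0059 tok0047 tok0010 tok0028 tok0003 tok0027 tok0003. tok0052 tok0002 tok0003 tok0014 tok0055 tok0009 tok0022 tok0029 tok0008."
"cat1_r0007","cat1","tok0038 tok0009 tok0003 tok0002 tok0002 tok0046 tok0003 tok0003. tok0003 tok0001 tok0002 tok0003 tok0003 tok0002. tok0051 tok0031 tok0051 tok0003 tok0054 tok0048 tok0027 tok0026."
"cat1_r0008","cat1","tok0001 tok0060 tok0039 tok0002. tok0027 tok0034 tok0019 tok0003 tok0003 tok0035."
"cat1_r0009","cat1","tok0002 tok0037 tok0046 tok0001 tok0035 tok0003 tok0002. tok0012 tok0007 tok0058. tok0002 tok0003 tok0019 tok0047 tok0003 tok0059 tok0018 tok0002."
"cat1_r0010","cat1","tok0002 tok0026 tok0001 tok0048 tok0003 tok0003 tok0015. tok0006 tok0059 tok0044 tok0047 tok0001 tok0002 tok0017. tok0018 tok0016 tok0047 tok0024 tok0016 tok0047 tok0002. tok0016 tok0003 tok0003 tok0002."
"cat2_r0001","cat2","tok0022 tok0058 tok0018 tok0008. tok0032 tok0006 tok0059 tok0023 tok0006 tok0005."
"cat2_r0002","cat2","tok0005 tok0005 tok0054 tok0005 tok0016 tok0003. tok0039 tok0006 tok0006 tok0050 tok0030 tok0006 tok0037 tok0027. tok0005 tok0005 tok0017."
"cat2_r0003","cat2","tok0017 tok0005 tok0004 tok0006 tok0028 tok0048 tok0004. tok0006 tok0013 tok0043. tok0059 tok0038 tok0005 tok0006 tok0004 tok0004 tok0027 tok0006 tok0008."
"cat2_r0004","cat2","tok0060 tok0021 tok0005 tok0004 tok0004 tok0015. tok0023 tok0006 tok0004 tok0015 tok0013 tok0002 tok0004."
"cat2_r0005","cat2","tok0004 tok0043 tok0015 tok0058 tok0033 tok0028. tok0006 tok0004 tok0027 tok0032."
"cat2_r0006","cat2","tok0006 tok0052 tok0004 tok0005 tok0005 tok0053. tok0056 tok0022 tok0050 tok0048. tok0018 tok0006 tok0004 tok0035 tok0006 tok0021 tok0052 tok0005. tok0019 tok0006 tok0006 tok0001 tok0003 tok0005 tok0040. tok0001 tok0047 tok0004 tok0003."
"cat2_r0007","cat2","tok0014 tok0004 tok0004 tok0008 tok0018 tok0005 tok0018. tok0058 tok0006 tok0005 tok0051 tok0004 tok0022 tok0005 tok0036."
"cat2_r0008","cat2","tok0006 tok0054 tok0006. tok0001 tok0005 tok0052 tok0010 tok0045 tok0029 tok0006 tok0056. tok0031 tok0042 tok0005 tok0060 tok0005. tok0004 tok0004 tok0006 tok0042."
"cat2_r0009","cat2","tok0042 tok0005 tok0014 tok0006 tok0028. tok0004 tok0003 tok0018 tok0004 tok0033. tok0038 tok0005 tok0005 tok0005 tok0054 tok0005 tok0004."
"cat2_r0010","cat2","tok0030 tok0006 tok0011 tok0005."
"cat3_r0001","cat3","tok0002 tok0009 tok0008 tok0045 tok0009 tok0019 tok0007. tok0007 tok0048 tok0026 tok0026."
"cat3_r0002","cat3","tok0008 tok0009 tok0008 tok0003."
"cat3_r0003","cat3","tok0009 tok0056 tok0009 tok0040 tok0009 tok0010 tok0009. tok0003 tok0009 tok0008. tok0039 tok0003 tok0009 tok0005 tok0007 tok0007 tok0007. tok0002 tok0049 tok0007 tok0024."
"cat3_r0004","cat3","tok0008 tok0032 tok0020 tok0009 tok0019 tok0009 tok0034 tok0024 tok0007 tok0008. tok0009 tok0008 tok0009 tok0007 tok0044 tok0009 tok0007 tok0007 tok0009."
"cat3_r0005","cat3","tok0048 tok0008 tok0009 tok0053 tok0007 tok0008 tok0009. tok0001 tok0008 tok0046 tok0009 tok0008 tok0029 tok0060. tok0009 tok0036 tok0008 tok0009 tok0012 tok0007 tok0025 tok0008."
"cat3_r0006","cat3","tok0009 tok0008 tok0007 tok0009 tok0017 tok0017 tok0054 tok0022. tok0009 tok0007 tok0008 tok0008 tok0034 tok0008. tok0019 tok0028 tok0027 tok0007 tok0009. tok0049 tok0008 tok0009 tok0059."
"cat3_r0007","cat3","tok0026 tok0007 tok0031 tok0003. tok0007 tok0007 tok0008 tok0009 tok0009 tok0026. tok0032 tok0017 tok0008 tok0008. tok0008 tok0058 tok0026 tok0042 tok0008 tok0009. tok0007 tok0050 tok0014 tok0008 tok0007 tok0039 tok0009."
"cat3_r0008","cat3","tok0009 tok0030 tok0046 tok0007 tok0007. tok0025 tok0007 tok0009 tok0008 tok0007 tok0008 tok0045. tok0007 tok0056 tok0009 tok0009. tok0048 tok0036 tok0008 tok0009 tok0013."
"cat3_r0009","cat3","tok0007 tok0050 tok0009 tok0008 tok0009 tok0034 tok0009 tok0008. tok0037 tok0007 tok0007 tok0031 tok0007 tok0025 tok0009 tok0026 tok0009 tok0009 tok0022. tok0008 tok0010 tok0037 tok0046."
"cat3_r0010","cat3","tok0055 tok0008 tok0048 tok0008 tok0014 tok0007 tok0030 tok0009. tok0009 tok0008 tok0007. tok0007 tok0026 tok0008 tok0006 tok0040 tok0009 tok0007 tok0046 tok0008."
"cat4_r0001","cat4","tok0012 tok0012 tok0012. tok0005 tok0046 tok0017 tok0005 tok0011 tok0003 tok0010 tok0010. tok0012 tok0009 tok0049 tok0010."
"cat4_r0002","cat4","tok0012 tok0024 tok0056 tok0010 tok0035. tok0037 tok0016 tok0012 tok0012 tok0021 tok0002 tok0033. tok0030 tok0016 tok0011 tok0057 tok0024 tok0012 tok0041. tok0010 tok0012 tok0009. tok0017 tok0010 tok0055."
"cat4_r0003","cat4","tok0031 tok0022 tok0059 tok0018. tok0021 tok0042 tok0011 tok0015 tok0010 tok0007. tok0012 tok0011 tok0011 tok0010."
"cat4_r0004","cat4","tok0010 tok0048 tok0022 tok0039 tok0022 tok0017. tok0012 tok0001 tok0012 tok0012 tok0011 tok0030."
"cat4_r0005","cat4","tok0015 tok0054 tok0010 tok0024 tok0011 tok0012 tok0016. tok0012 tok0001 tok0009 tok0031 tok0056 tok0043 tok0052. tok0011 tok0051 tok0010 tok0019 tok0012 tok0052. tok0028 tok0011 tok0010 tok0032 tok0049 tok0011 tok0047 tok0008."
"cat4_r0006","cat4","tok0012 tok0010 tok0011 tok0011 tok0022 tok0022 tok0057 tok0047 tok0052. tok0012 tok0009 tok0013 tok0011 tok0030 tok0033."
"cat4_r0007","cat4","tok0010 tok0054 tok0014 tok0028."
"cat4_r0008","cat4","tok0033 tok0026 tok0012 tok0025 tok0011 tok0012 tok0035 tok0034. tok0011 tok0010 tok0013 tok0012 tok0024 tok0010 tok0030. tok0010 tok0012 tok0044 tok0011 tok0002 tok0051 tok0039."
"cat4_r0009","cat4","tok0060 tok0018 tok0043 tok0013 tok0012. tok0049 tok0010 tok0005 tok0018 tok0025 tok0012. tok0010 tok0033 tok0060 tok0025. tok0011 tok0037 tok0059 tok0028 tok0020 tok0020 tok0012 tok0011 tok0011 tok0001 tok0048."
"cat4_r0010","cat4","tok0011 tok0053 tok0057 tok0010 tok0011. tok0013 tok0028 tok0012 tok0012 tok0011 tok0011 tok0013 tok0047 tok0040 tok0006. tok0030 tok0050 tok0011 tok0060 tok0011 tok0058."
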