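country,year,nmr,imr,u5mr,nmr_lower,nmr_upper,imr_lower,imr_upper,u5mr_lower,u5mr_upper
SYNTHETIC,1993,57.2,158.9,208.3,52.6,61.8,146.2,171.6,191.6,224.9
SYNTHETIC,1994,56.4,156.6,204.5,51.8,60.9,144.1,169.1,188.1,220.9
SYNTHETIC,1995,55.5,154.3,200.8,51.1,60,142,166.6,184.7,216.9
SYNTHETIC,1996,54.7,152,197.2,50.4,59.1,139.9,164.2,181.4,213
SYNTHETIC,1997,53.9,149.8,193.6,49.6,58.3,137.8,161.8,178.1,209.1
SYNTHETIC,1998,53.2,147.6,190.1,48.9,57.4,135.8,159.4,174.9,205.4
SYNTHETIC,1999,52.4,145.5,186.7,48.2,56.6,133.8,157.1,171.8,201.7
SYNTHETIC,2000,51.6,143.3,183.4,47.5,55.8,131.9,154.8,168.7,198
SYNTHETIC,2001,50.9,141.2,180.1,46.8,54.9,129.9,152.5,165.7,194.5
SYNTHETIC,2002,50.1,139.1,176.9,46.1,54.2,128,150.3,162.7,191
SYNTHETIC,2003,49.4,137.1,173.7,45.5,53.4,126.1,148,159.8,187.6
SYNTHETIC,2004,48.7,135.1,170.6,44.8,52.6,124.3,145.9,157,184.3
SYNTHETIC,2005,48,133.1,167.6,44.1,51.8,122.4,143.7,154.2,181
SYNTHETIC,2006,47.3,131.1,164.6,43.5,51.1,120.6,141.6,151.4,177.7
SYNTHETIC,2007,46.6,129.2,161.6,42.9,50.3,118.8,139.5,148.7,174.6
SYNTHETIC,2008,45.9,127.2,158.8,42.3,49.6,117.1,137.4,146.1,171.5
SYNTHETIC,2009,45.3,125.4,156,41.6,48.9,115.3,135.4,143.5,168.4
SYNTHETIC,2010,44.6,123.5,153.2,41,48.2,113.6,133.4,140.9,165.4
SYNTHETIC,2011,43.9,121.7,150.5,40.4,47.5,111.9,131.4,138.4,162.5
SYNTHETIC,2012,43.3,119.8,147.8,39.8,46.8,110.3,129.4,136,159.6
SYNTHETIC,2013,42.7,118.1,145.2,39.3,46.1,108.6,127.5,133.6,156.8
SYNTHETIC,2014,42.1,116.3,142.6,38.7,45.4,107,125.6,131.2,154.1
SYNTHETIC,2015,41.4,114.6,140.1,38.1,44.8,105.4,123.7,128.9,151.3
SYNTHETIC,2016,40.8,112.9,137.7,37.6,44.1,103.8,121.9,126.7,148.7
SYNTHETIC,2017,40.2,111.2,135.3,37,43.5,102.3,120.1,124.4,146.1
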